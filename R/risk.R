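# Threshold-based pathogenicity classification of externally supplied
# SIFT / PolyPhen scores, and screening for published ROS-associated and
# primary-LHON variant sets.  Scores are always inputs: nothing here
# computes a SIFT or PolyPhen value.

#' ROS-associated and primary LHON variant sets
#'
#' `ros_variant_set()`: substitutions reported in association with
#' elevated reactive-oxygen-species production (G10398A, A12308G,
#' G13708A).  `lhon_variant_set()`: the three primary LHON mutations
#' (G3460A, G11778A, T14484C).
#'
#' @return A `mito_variant` data frame.
#' @export
ros_variant_set <- function() {
  variant(c(10398L, 12308L, 13708L), c("G", "A", "G"), c("A", "G", "A"))
}

#' @rdname ros_variant_set
#' @export
lhon_variant_set <- function() {
  variant(c(3460L, 11778L, 14484L), c("G", "G", "T"), c("A", "A", "C"))
}

#' Classify SIFT / PolyPhen scores into pathogenicity calls
#'
#' Thresholds:
#' * SIFT: `< 0.05` deleterious, `>= 0.05` tolerated (boundary 0.05 is
#'   tolerated);
#' * PolyPhen (PSIC / PHAT difference): `> 2.0` probably damaging,
#'   `[1.5, 2.0]` possibly damaging (closed bracket: 1.5 and 2.0 are
#'   both possibly damaging), `< 1.5` benign.
#'
#' The combined call is `pathogenic` iff SIFT is deleterious AND PolyPhen
#' is at least possibly damaging; this conjunctive policy reflects
#' variants reported pathogenic under both tools, and is exposed via
#' `combine`.
#'
#' @param sift_score Numeric in `[0, 1]` or `NA` (absent).
#' @param polyphen_score Non-negative numeric or `NA` (absent).
#' @param combine `"both"` (default: deleterious AND damaging) or
#'   `"either"`.
#' @return List of class `pathogenicity_call` with `sift_call`
#'   (`deleterious` / `tolerated` / `absent`), `polyphen_call`
#'   (`probably_damaging` / `possibly_damaging` / `benign` / `absent`)
#'   and `combined` (`pathogenic` / `not_pathogenic`).
#' @examples
#' classify_scores(0.04, 2.3)$combined  # "pathogenic"
#' classify_scores(0.05, 1.49)$combined # "not_pathogenic"
#' @export
classify_scores <- function(sift_score = NA_real_, polyphen_score = NA_real_,
                            combine = c("both", "either")) {
  combine <- match.arg(combine)
  if (is.na(sift_score) && is.na(polyphen_score))
    stop("at least one score must be present")
  if (!is.na(sift_score) && (sift_score < 0 || sift_score > 1))
    stop("SIFT score must be in [0, 1], got ", sift_score)
  if (!is.na(polyphen_score) && polyphen_score < 0)
    stop("PolyPhen score must be non-negative, got ", polyphen_score)
  sift_call <- if (is.na(sift_score)) "absent"
               else if (sift_score < 0.05) "deleterious" else "tolerated"
  polyphen_call <- if (is.na(polyphen_score)) "absent"
                   else if (polyphen_score > 2.0) "probably_damaging"
                   else if (polyphen_score >= 1.5) "possibly_damaging"
                   else "benign"
  damaging <- polyphen_call %in% c("probably_damaging", "possibly_damaging")
  deleterious <- sift_call == "deleterious"
  combined <- if (combine == "both") deleterious && damaging
              else deleterious || damaging
  structure(list(sift_call = sift_call, polyphen_call = polyphen_call,
                 combined = if (combined) "pathogenic" else "not_pathogenic"),
            class = "pathogenicity_call")
}

#' Screen variants against the ROS and LHON sets
#'
#' Membership is decided purely on the (position, ref, alt) triple.
#'
#' @param v A `mito_variant` data frame.
#' @return Data frame with columns `position`, `ref`, `alt`,
#'   `ros_associated`, `lhon_primary`.
#' @examples
#' screen_special_sets(variant(10398, "G", "A"))
#' @export
screen_special_sets <- function(v) {
  key <- function(d) paste(d$position, toupper(d$ref), toupper(d$alt))
  data.frame(position = v$position, ref = v$ref, alt = v$alt,
             ros_associated = key(v) %in% key(ros_variant_set()),
             lhon_primary = key(v) %in% key(lhon_variant_set()),
             stringsAsFactors = FALSE)
}

#' Read a pathogenicity score TSV
#'
#' Columns: `position`, `ref`, `alt`, `sift_score`, `polyphen_score`
#' (either score column may be `NA`).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("scores TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$sift_score)) df$sift_score <- NA_real_
  if (is.null(df$polyphen_score)) df$polyphen_score <- NA_real_
  df
}

#' Per-patient and cohort-level risk summary
#'
#' For each subject: does it carry any pathogenic variant (per supplied
#' score classifications), any ROS-associated variant, any primary LHON
#' mutation?  Cohort counts and percentages (display-rounded to 2
#' decimals) are attached.
#'
#' @param cohort List of per-subject `mito_variant` data frames (any data
#'   frame with `position`, `ref`, `alt` columns).
#' @param pathogenic_variants Optional `mito_variant` data frame of
#'   variants classified pathogenic.
#' @return List with `per_patient` (data frame: `subject`,
#'   `any_pathogenic`, `any_ros`, `any_lhon`) and `cohort` (counts and
#'   percentages).
#' @export
patient_risk_summary <- function(cohort, pathogenic_variants = NULL) {
  key <- function(d) paste(d$position, toupper(d$ref), toupper(d$alt))
  path_keys <- if (is.null(pathogenic_variants)) character(0)
               else key(pathogenic_variants)
  per <- lapply(seq_along(cohort), function(i) {
    k <- key(cohort[[i]])
    data.frame(subject = i,
               any_pathogenic = any(k %in% path_keys),
               any_ros = any(k %in% key(ros_variant_set())),
               any_lhon = any(k %in% key(lhon_variant_set())))
  })
  per <- if (length(per)) do.call(rbind, per)
         else data.frame(subject = integer(0), any_pathogenic = logical(0),
                         any_ros = logical(0), any_lhon = logical(0))
  n <- max(length(cohort), 1L)
  counts <- c(pathogenic = sum(per$any_pathogenic),
              ros = sum(per$any_ros), lhon = sum(per$any_lhon))
  list(per_patient = per,
       cohort = list(n = length(cohort), counts = counts,
                     percent = round(100 * counts / n, 2)))
}
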