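#' Construct an expression study
#'
#' Bundles a log2 probe-by-sample expression matrix with its per-sample
#' design annotations (subject, sex, arm, time) and validates the pairing
#' structure the downstream contrasts rely on.
#'
#' @param values Numeric matrix of log2 intensities, probes in rows (unique
#'   rownames), samples in columns (unique colnames). All values finite.
#' @param design Data frame with columns `sample_id`, `subject_id`, `sex`
#'   (`"M"`/`"F"`), `arm` (`"exercised"`/`"control"`), `time` (`"baseline"`,
#'   `"4h"` or `"24h"`). Every column of `values` must have a design row.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to `values` (for
#'   raw-scale input); the default assumes the matrix is already
#'   log2-summarized.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` and `design`.
#' @export
expression_study <- function(values, design, log2_transform = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L], call. = FALSE)
  if (log2_transform) {
    if (any(values < 0)) stop("negative values cannot be log2(x+1)-transformed",
                              call. = FALSE)
    values <- log2(values + 1)
  }
  if (!all(is.finite(values)))
    stop("non-finite expression values are not supported", call. = FALSE)
  design <- validate_design(design)
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  cat("  subjects:", length(unique(x$design$subject_id)),
      " sex M/F:", sum(tapply(x$design$sex, x$design$subject_id,
                              function(s) s[1L]) == "M"), "/",
      sum(tapply(x$design$sex, x$design$subject_id,
                 function(s) s[1L]) == "F"), "\n")
  invisible(x)
}

design_levels <- list(sex  = c("M", "F"),
                      arm  = c("exercised", "control"),
                      time = c("baseline", "4h", "24h"))

validate_design <- function(design) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "sex", "arm", "time")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  design <- design[need]
  for (col in names(design_levels)) {
    bad <- setdiff(unique(design[[col]]), design_levels[[col]])
    if (length(bad))
      stop("invalid ", col, " value '", bad[1L], "'; allowed: ",
           paste(design_levels[[col]], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample id in design: ",
         design$sample_id[duplicated(design$sample_id)][1L], call. = FALSE)
  # a subject may contribute at most one sample per arm within a time group
  key <- paste(design$subject_id, design$arm, design$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- design[duplicated(key), , drop = FALSE]
    stop("subject ", d$subject_id[1L], " has two '", d$arm[1L],
         "' samples at time ", d$time[1L], call. = FALSE)
  }
  design
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row (`probe_id` followed by sample ids) and a numeric
#' body; row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression table needs a probe_id column and >=1 sample", call. = FALSE)
  probes <- raw[[1L]]
  if (anyDuplicated(probes))
    stop("duplicate probe id '", probes[duplicated(probes)][1L],
         "' in ", path, call. = FALSE)
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id '", samples[duplicated(samples)][1L],
         "' in ", path, call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", body[idx[1L], idx[2L]], "' at row ", idx[1L],
         " (probe ", probes[idx[1L]], "), column ", idx[2L], " (sample ",
         samples[idx[2L]], ")", call. = FALSE)
  }
  dimnames(vals) <- list(probes, samples)
  vals
}

#' Write an expression matrix as TSV at full double precision
#'
#' @param values Numeric matrix with dimnames, or an `expression_study`.
#' @param path Output path. UTF-8, LF line endings, `%.17g` formatting so a
#'   read/write round trip is bit-exact for finite doubles.
#' @export
write_expression_table <- function(values, path) {
  if (inherits(values, "expression_study")) values <- values$values
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(values, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(values))
  writeLines(paste(rownames(values), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Read a sample-design table
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `sex`, `arm`,
#'   `time`; category values are validated.
#' @return Validated design data frame.
#' @export
read_design_table <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  validate_design(design)
}

#' @rdname read_design_table
#' @param design Design data frame.
#' @export
write_design_table <- function(design, path) {
  design <- validate_design(design)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(design), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(design, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the identical distribution: the across-column
#' mean of order statistics. Ties within a column receive the mean of the
#' target order statistics over their rank span (average-rank convention),
#' which makes the transform deterministic and idempotent.
#'
#' @param values Numeric matrix with at least one column, all values finite.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L)
    stop("cannot quantile-normalize an empty matrix", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  target <- rowMeans(apply(values, 2L, sort))
  out <- apply(values, 2L, function(col) {
    v <- target[rank(col, ties.method = "first")]
    if (anyDuplicated(col)) v <- stats::ave(v, match(col, col), FUN = mean)
    v
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Define a two-group comparison over the study design
#'
#' A comparison names a case and a reference group via design-field
#' selectors, e.g. exercised vs control arms within the male 24 h group
#' (paired) or male vs female control arms (unpaired).
#'
#' @param name Label used in outputs.
#' @param mode `"paired"` (within-subject case minus reference) or
#'   `"unpaired"` (group mean difference).
#' @param case,reference Named lists of design filters; each element is a
#'   vector of allowed values for the design field of that name (fields:
#'   `sex`, `arm`, `time`, `subject_id`). A field left out is unconstrained.
#' @return Object of class `comparison`.
#' @export
comparison <- function(name, mode = c("paired", "unpaired"), case, reference) {
  mode <- match.arg(mode)
  ok <- c("sex", "arm", "time", "subject_id")
  for (sel in list(case, reference)) {
    if (!is.list(sel) || is.null(names(sel)) || !all(names(sel) %in% ok))
      stop("selectors must be named lists over fields: ",
           paste(ok, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, mode = mode, case = case, reference = reference),
            class = "comparison")
}

match_selector <- function(design, selector) {
  keep <- rep(TRUE, nrow(design))
  for (field in names(selector))
    keep <- keep & design[[field]] %in% selector[[field]]
  keep
}

#' The default five-comparison template
#'
#' One unpaired baseline contrast (male vs female control arms, pooled over
#' biopsy times) and four paired exercised-vs-control contrasts, one per
#' sex and recovery time point.
#'
#' @return List of five `comparison` objects.
#' @export
default_comparisons <- function() {
  paired <- function(sex, time)
    comparison(paste0(ifelse(sex == "M", "male", "female"), "_", time),
               "paired",
               case = list(sex = sex, time = time, arm = "exercised"),
               reference = list(sex = sex, time = time, arm = "control"))
  list(comparison("baseline_M_vs_F", "unpaired",
                  case = list(sex = "M", arm = "control"),
                  reference = list(sex = "F", arm = "control")),
       paired("M", "4h"), paired("M", "24h"),
       paired("F", "4h"), paired("F", "24h"))
}

#' Resolve the samples a comparison uses
#'
#' @param study An `expression_study`.
#' @param cmp A `comparison`.
#' @return For unpaired mode, a list with `case` and `reference` sample ids.
#'   For paired mode, additionally aligned by subject: `subjects`, and
#'   case/reference ids in matching order (incomplete pairs dropped).
#' @export
comparison_samples <- function(study, cmp) {
  d <- study$design
  case <- d$sample_id[match_selector(d, cmp$case)]
  ref  <- d$sample_id[match_selector(d, cmp$reference)]
  if (length(intersect(case, ref)))
    stop("comparison '", cmp$name, "': case and reference selectors overlap",
         call. = FALSE)
  if (cmp$mode == "unpaired") {
    if (length(case) < 2L || length(ref) < 2L)
      stop("comparison '", cmp$name,
           "': unpaired mode needs >=2 samples per group", call. = FALSE)
    return(list(mode = "unpaired", case = case, reference = ref))
  }
  subj_case <- d$subject_id[match(case, d$sample_id)]
  subj_ref  <- d$subject_id[match(ref, d$sample_id)]
  shared <- intersect(subj_case, subj_ref)
  if (length(shared) < 2L)
    stop("comparison '", cmp$name, "': paired mode needs >=2 complete ",
         "subject pairs (found ", length(shared), ")", call. = FALSE)
  shared <- sort(shared)
  list(mode = "paired", subjects = shared,
       case = case[match(shared, subj_case)],
       reference = ref[match(shared, subj_ref)])
}
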