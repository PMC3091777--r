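#' Relative quantification by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per well group; the target Ct is
#' normalized to the reference gene within each condition
#' (`dCt = Ct_target - Ct_reference`), conditions are differenced
#' (`ddCt = dCt_exercised - dCt_control`) and the fold change is
#' `2^-ddCt` (amplification efficiency taken as exactly 2). A fold above
#' 1 therefore corresponds to a negative ddCt.
#'
#' @param ct_target_case,ct_ref_case Replicate Ct values for the target
#'   and reference gene in the case (exercised) condition.
#' @param ct_target_ref,ct_ref_ref The same for the reference (control)
#'   condition.
#' @return List with `ddct`, `fold` and `log2_fold` (`= -ddct`).
#' @export
ddct_fold <- function(ct_target_case, ct_ref_case,
                      ct_target_ref, ct_ref_ref) {
  for (v in list(ct_target_case, ct_ref_case, ct_target_ref, ct_ref_ref)) {
    if (length(v) < 1L || anyNA(v))
      stop("missing Ct values (target and reference wells are required ",
           "for both conditions)", call. = FALSE)
    if (any(v <= 0)) stop("Ct values must be positive", call. = FALSE)
  }
  dct_case <- mean(ct_target_case) - mean(ct_ref_case)
  dct_ref <- mean(ct_target_ref) - mean(ct_ref_ref)
  ddct <- dct_case - dct_ref
  list(ddct = ddct, fold = 2^(-ddct), log2_fold = -ddct)
}

#' Per-gene fold changes from a Ct panel
#'
#' Computes a 2^-ddCt fold per gene and subject, then summarizes each
#' gene across subjects as the arithmetic mean of per-subject log2 folds,
#' exponentiated (geometric-mean fold).
#'
#' @param panel Data frame with columns `gene`, `subject`, `condition`
#'   (`"exercised"`/`"control"`), `well_role` (`"target"`/`"reference"`),
#'   `ct`, one row per replicate well (the format
#'   [generate_qpcr_panel()] emits).
#' @return List with `per_subject` (data frame: gene, subject, ddct,
#'   fold) and `per_gene` (data frame: gene, n_subjects, log2_fold,
#'   fold).
#' @export
qpcr_fold_table <- function(panel) {
  need <- c("gene", "subject", "condition", "well_role", "ct")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("Ct panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  per_subject <- do.call(rbind, lapply(
    split(panel, panel[c("gene", "subject")], drop = TRUE),
    function(pp) {
      pick <- function(cond, role) pp$ct[pp$condition == cond &
                                           pp$well_role == role]
      r <- ddct_fold(pick("exercised", "target"),
                     pick("exercised", "reference"),
                     pick("control", "target"),
                     pick("control", "reference"))
      data.frame(gene = pp$gene[1L], subject = pp$subject[1L],
                 ddct = r$ddct, fold = r$fold, stringsAsFactors = FALSE)
    }))
  rownames(per_subject) <- NULL
  per_gene <- do.call(rbind, lapply(split(per_subject, per_subject$gene),
                                    function(g)
    data.frame(gene = g$gene[1L], n_subjects = nrow(g),
               log2_fold = mean(-g$ddct), fold = 2^mean(-g$ddct),
               stringsAsFactors = FALSE)))
  rownames(per_gene) <- NULL
  list(per_subject = per_subject, per_gene = per_gene)
}

#' Spearman rank concordance
#'
#' Rho is the Pearson correlation of average-tie ranks; the p-value uses
#' the t approximation on `n - 2` degrees of freedom, or the exact
#' permutation distribution when `exact = TRUE` and `n <= 9`.
#'
#' @param a,b Numeric vectors of equal length (>= 3 complete pairs).
#' @param exact Use the exact permutation null (only for `n <= 9`).
#' @return Object of class `concordance_result`: list with `rho`, `p`,
#'   `n`, `method`.
#' @export
spearman_concordance <- function(a, b, exact = FALSE) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined (constant input)"),
                     class = "concordance_result"))
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  if (exact && n <= 9L) {
    perms <- permutations_of(n)
    rb_sorted <- rb
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(ra, rb_sorted[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 1e-300
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- max(2 * stats::pt(-abs(tstat), df = n - 2), 1e-300)
    }
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Spearman concordance: rho =", format(x$rho, digits = 3),
      " p =", format(x$p, digits = 3), " n =", x$n,
      paste0("(", x$method, ")"), "\n")
  invisible(x)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Microarray vs qPCR fold-change concordance
#'
#' Assembles per-gene fold-change pairs -- the array side as `2^b` of the
#' gene's representative probe (highest mean intensity) from a moderated
#' result, the qPCR side as the per-gene 2^-ddCt fold -- and computes
#' their Spearman concordance. Results from several comparisons may be
#' supplied to accumulate gene-by-condition pairs, as when a validation
#' panel spans all sex-by-time conditions.
#'
#' @param results A `moderated_result` or (named) list of them.
#' @param qpcr_folds Either a Ct panel (columns as in
#'   [qpcr_fold_table()]) or its `per_gene` fold table.
#' @param gene_map Optional probe-to-gene map (columns `probe_id`,
#'   `gene_id`); by default probes are their own genes.
#' @return List with `pairs` (data frame: gene, comparison, fold_array,
#'   fold_qpcr) and `concordance` (a `concordance_result`).
#' @export
platform_concordance <- function(results, qpcr_folds, gene_map = NULL) {
  if (inherits(results, "moderated_result")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- vapply(seq_along(results), function(i) {
      nm <- attr(results[[i]], "comparison")
      if (is.null(nm)) paste0("comparison_", i) else nm
    }, "")
  if (!is.null(qpcr_folds$ct) || "well_role" %in% names(qpcr_folds))
    qpcr_folds <- qpcr_fold_table(qpcr_folds)$per_gene
  pairs <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    gene <- if (is.null(gene_map)) r$probe_id else
      gene_map$gene_id[match(r$probe_id, gene_map$probe_id)]
    # representative probe per gene: highest mean intensity
    keep <- unlist(lapply(split(seq_len(nrow(r)), gene),
                          function(i) i[which.max(r$a[i])]),
                   use.names = FALSE)
    r <- r[keep, , drop = FALSE]
    g <- if (is.null(gene_map)) r$probe_id else
      gene_map$gene_id[match(r$probe_id, gene_map$probe_id)]
    hit <- match(qpcr_folds$gene, g)
    ok <- !is.na(hit)
    if (!any(ok)) return(NULL)
    data.frame(gene = qpcr_folds$gene[ok], comparison = nm,
               fold_array = 2^r$b[hit[ok]],
               fold_qpcr = qpcr_folds$fold[ok],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("fewer than 3 overlapping gene-condition pairs", call. = FALSE)
  list(pairs = pairs,
       concordance = spearman_concordance(pairs$fold_array,
                                          pairs$fold_qpcr))
}
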