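#' Gene-set collection
#'
#' @param sets Named list of character vectors of member gene ids (names
#'   are set ids, unique).
#' @param descriptions Optional character vector of set names/descriptions
#'   (recycled if length 1).
#' @param namespace Optional namespace label per set (e.g. `"GO"`,
#'   `"KEGG"`).
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, namespace = NULL) {
  if (!is.list(sets) || is.null(names(sets)))
    stop("`sets` must be a named list", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set id: ", names(sets)[duplicated(names(sets))][1L],
         call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- names(sets)
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  if (!is.null(namespace)) {
    namespace <- rep_len(as.character(namespace), length(sets))
    names(namespace) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions,
                 namespace = namespace),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("gene_set_collection:", length(x$sets), "sets, sizes",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member ids`.
#' When a measured-gene `universe` is supplied, memberships are
#' intersected with it and sets left empty are dropped (with a message
#' giving the count).
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of measured gene ids.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], " (fewer than 3 fields) in ",
         path, call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, universe)
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      message(sum(empty), " set(s) empty after intersection with the ",
              "universe were dropped")
      sets <- sets[!empty]
      desc <- desc[!empty]
    }
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path (UTF-8, LF).
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(collection$sets), function(id)
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t"), ""), con, sep = "\n")
  invisible(path)
}

#' Build signed log significance scores
#'
#' Each gene's enrichment covariate is `x = sign * (-log(p))` with the
#' natural logarithm: an up-regulated gene with a small p-value gets a
#' large positive score, a down-regulated one a large negative score, and
#' `p = 1` gives zero regardless of direction. P-values are clamped to
#' `[1e-300, 1]` before the log. At `level = "gene"`, genes measured by
#' several probes are represented by the probe with the highest mean
#' signal intensity.
#'
#' @param result A `moderated_result` from [moderated_test()].
#' @param gene_map Optional data frame with columns `probe_id`, `gene_id`
#'   mapping probes to genes; required for `level = "gene"` unless probes
#'   are their own genes.
#' @param level `"probe"` (default) or `"gene"`.
#' @return Object of class `significance_scores`: data frame with columns
#'   `id`, `x`, `p`, `sign` (one row per probe or gene).
#' @export
build_significance_scores <- function(result, gene_map = NULL,
                                      level = c("probe", "gene")) {
  level <- match.arg(level)
  stopifnot(inherits(result, "moderated_result"))
  res <- result[!result$flagged & !is.na(result$p), , drop = FALSE]
  if (nrow(res) == 0L) stop("no tested probes with p-values", call. = FALSE)
  if (level == "gene") {
    gene <- if (is.null(gene_map)) res$probe_id else {
      g <- gene_map$gene_id[match(res$probe_id, gene_map$probe_id)]
      if (anyNA(g)) stop("gene_map does not cover all probes", call. = FALSE)
      g
    }
    # representative probe per gene: highest mean intensity
    keep <- unlist(lapply(split(seq_len(nrow(res)), gene),
                          function(i) i[which.max(res$a[i])]),
                   use.names = FALSE)
    res <- res[keep, , drop = FALSE]
    ids <- if (is.null(gene_map)) res$probe_id else
      gene_map$gene_id[match(res$probe_id, gene_map$probe_id)]
  } else ids <- res$probe_id
  p <- pmin(pmax(res$p, 1e-300), 1)
  out <- data.frame(id = ids, x = res$sign * (-log(p)), p = p,
                    sign = res$sign, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("significance_scores", "data.frame"),
            level = level, comparison = attr(result, "comparison"))
}

# Two-parameter logistic regression of membership on the score by
# iteratively reweighted least squares. Deterministic failure modes:
# non-convergence within max_iter or a slope past the separation bound
# marks the fit unstable.
logistic_irls <- function(x, y, max_iter = 50L, tol = 1e-10,
                          beta_bound = 20) {
  n <- length(x)
  deviance_at <- function(beta) {
    mu <- pmin(pmax(stats::plogis(beta[1L] + beta[2L] * x), 1e-12),
               1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  beta <- c(log(max(mean(y), 1e-8) / max(1 - mean(y), 1e-8)), 0)
  dev <- deviance_at(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- beta[1L] + beta[2L] * x
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
    det <- sw * swx2 - swx^2
    if (!is.finite(det) || det <= 0) break
    swz <- sum(w * z); swxz <- sum(w * x * z)
    beta_new <- c((swx2 * swz - swx * swxz) / det,
                  (sw * swxz - swx * swz) / det)
    # guard the Newton step: halve it while the deviance worsens, which
    # keeps fits with very long score tails from diverging
    dev_new <- deviance_at(beta_new)
    halvings <- 0L
    while ((!is.finite(dev_new) || dev_new > dev + 1e-10) &&
           halvings < 20L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- deviance_at(beta_new)
      halvings <- halvings + 1L
    }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    dev <- dev_new
    if (is.finite(step) && step < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  unstable <- !converged || abs(beta[2L]) > beta_bound
  # Wald SE from the inverse Fisher information at the final fit
  eta <- beta[1L] + beta[2L] * x
  mu <- stats::plogis(eta)
  w <- pmin(pmax(mu * (1 - mu), 1e-12), 0.25)
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  det <- sw * swx2 - swx^2
  se <- if (is.finite(det) && det > 0) sqrt(sw / det) else NA_real_
  list(beta0 = beta[1L], beta1 = beta[2L], se = se,
       converged = converged, unstable = unstable)
}

#' Cutoff-free gene-set enrichment by logistic regression (LRpath)
#'
#' For each gene set, fits `logit P(member) = beta0 + beta1 * x` over the
#' whole measured universe, where `x` is the signed log significance
#' score; a positive slope means set members concentrate among
#' significantly up-regulated genes. The slope is tested by a two-sided
#' Wald test and the set family is adjusted by [bh_fdr()]. Nondirectional
#' mode uses the unsigned score `-log(p)`.
#'
#' @param scores A `significance_scores` object.
#' @param sets A `gene_set_collection`.
#' @param min_size,max_size Set-size window after restriction to the
#'   universe; sets outside it are not tested.
#' @param directional If `FALSE`, use `|x| = -log(p)` (enrichment with
#'   significance regardless of direction).
#' @param fdr_threshold FDR below which `enriched` is flagged.
#' @return Object of class `enrichment_result`: data frame with one row
#'   per tested set: `set_id`, `name`, `n`, `beta1`, `odds_ratio`
#'   (per unit of log-p score), `direction`, `wald`, `p`, `fdr`,
#'   `enriched`, `status` (`"ok"` or `"unstable"`).
#' @export
run_lrpath <- function(scores, sets, min_size = 10L, max_size = 500L,
                       directional = TRUE, fdr_threshold = 0.01) {
  stopifnot(inherits(scores, "significance_scores"),
            inherits(sets, "gene_set_collection"))
  universe <- scores$id
  if (anyDuplicated(universe)) stop("duplicate ids in scores", call. = FALSE)
  x <- if (directional) scores$x else -log(pmin(pmax(scores$p, 1e-300), 1))
  if (length(unique(x)) < 2L)
    stop("degenerate scores: the significance score is constant over the ",
         "universe", call. = FALSE)
  members <- lapply(sets$sets, intersect, universe)
  n_s <- lengths(members)
  test <- which(n_s >= min_size & n_s <= max_size)
  if (!length(test))
    stop("no sets within the size window [", min_size, ", ", max_size, "]",
         call. = FALSE)
  rows <- lapply(test, function(i) {
    y <- as.numeric(universe %in% members[[i]])
    if (all(y == 1) || all(y == 0))
      return(data.frame(beta1 = NA_real_, se = NA_real_, wald = NA_real_,
                        p = NA_real_, status = "unstable",
                        stringsAsFactors = FALSE))
    fit <- logistic_irls(x, y)
    if (fit$unstable || !is.finite(fit$se) || fit$se <= 0)
      return(data.frame(beta1 = fit$beta1, se = fit$se, wald = NA_real_,
                        p = NA_real_, status = "unstable",
                        stringsAsFactors = FALSE))
    wald <- fit$beta1 / fit$se
    data.frame(beta1 = fit$beta1, se = fit$se, wald = wald,
               p = max(2 * stats::pnorm(-abs(wald)), 1e-300),
               status = "ok", stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  out <- data.frame(set_id = names(sets$sets)[test],
                    name = unname(sets$descriptions[test]),
                    n = unname(n_s[test]),
                    beta1 = fits$beta1,
                    odds_ratio = exp(fits$beta1),
                    direction = ifelse(is.na(fits$beta1), NA_character_,
                                       ifelse(fits$beta1 >= 0, "up", "down")),
                    se = fits$se, wald = fits$wald, p = fits$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out$enriched <- !is.na(out$fdr) & out$fdr < fdr_threshold
  out$status <- fits$status
  structure(out, class = c("enrichment_result", "data.frame"),
            directional = directional, min_size = min_size,
            max_size = max_size, fdr_threshold = fdr_threshold,
            comparison = attr(scores, "comparison"))
}

#' Signed enrichment matrix across comparisons
#'
#' Builds the terms-by-comparisons matrix used for cross-condition
#' clustering: entry = direction sign times `-log10(p)` of the set's
#' enrichment in that comparison; a term untested or unstable in a
#' comparison contributes 0.
#'
#' @param results Named list of `enrichment_result` objects, one per
#'   comparison (names become column names, in list order).
#' @param enriched_only If `TRUE`, keep only terms flagged enriched in at
#'   least one comparison.
#' @return Numeric matrix, terms in rows, comparisons in columns.
#' @export
enrichment_matrix <- function(results, enriched_only = FALSE) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (is.null(names(results)))
    names(results) <- paste0("comparison_", seq_along(results))
  terms <- unique(unlist(lapply(results, `[[`, "set_id")))
  mat <- matrix(0, length(terms), length(results),
                dimnames = list(terms, names(results)))
  for (j in seq_along(results)) {
    r <- results[[j]]
    ok <- !is.na(r$p)
    val <- ifelse(r$direction[ok] == "up", 1, -1) * (-log10(r$p[ok]))
    mat[r$set_id[ok], j] <- val
  }
  if (enriched_only) {
    keep <- unique(unlist(lapply(results,
                                 function(r) r$set_id[r$enriched])))
    mat <- mat[terms %in% keep, , drop = FALSE]
  }
  mat
}

#' Write a signed enrichment matrix as TSV
#'
#' @param mat Matrix from [enrichment_matrix()].
#' @param path Output path.
#' @export
write_enrichment_matrix <- function(mat, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("term", colnames(mat)), collapse = "\t"), con, sep = "\n")
  writeLines(paste(rownames(mat),
                   apply(mat, 1L, function(r)
                     paste(sprintf("%.17g", r), collapse = "\t")),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}
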