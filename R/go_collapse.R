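#' Term DAG of parent-child relations
#'
#' @param edges Data frame with columns `child`, `parent` (term ids).
#' @param nodes Optional character vector of known term ids; defaults to
#'   the ids appearing in `edges`. Edges must connect known nodes and the
#'   graph must be acyclic.
#' @return Object of class `term_dag`.
#' @export
term_dag <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(edges)))
    stop("edges need columns `child` and `parent`", call. = FALSE)
  edges <- edges[c("child", "parent")]
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  if (is.null(nodes)) nodes <- unique(c(edges$child, edges$parent))
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(c(edges$child, edges$parent), nodes)
  if (length(unknown))
    stop("edge references unknown node: ", unknown[1L], call. = FALSE)
  cyc <- find_cycle(edges, nodes)
  if (!is.null(cyc))
    stop("term graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "term_dag")
}

# Kahn topological sort on child->parent edges; returns NULL if acyclic,
# otherwise one offending cycle (walked through the leftover subgraph).
find_cycle <- function(edges, nodes) {
  out_deg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  out_deg[names(tab)] <- as.integer(tab)
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  queue <- names(out_deg)[out_deg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children_of[[v]]) {
      out_deg[ch] <- out_deg[ch] - 1L
      if (out_deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(nodes)) return(NULL)
  start <- names(out_deg)[out_deg > 0L][1L]
  path <- start
  v <- start
  repeat {
    nxt <- intersect(parents_of[[v]], names(out_deg)[out_deg > 0L])[1L]
    if (nxt %in% path)
      return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
    v <- nxt
  }
}

#' @export
print.term_dag <- function(x, ...) {
  cat("term_dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a term DAG from a two-column TSV
#'
#' @param path TSV with header columns `child`, `parent` (header optional:
#'   a first line without the literal column names is treated as data).
#' @return A `term_dag`; cycles are rejected with one offending cycle
#'   named.
#' @export
read_dag <- function(path) {
  first <- readLines(path, n = 1L)
  header <- identical(strsplit(first, "\t", fixed = TRUE)[[1L]][1:2],
                      c("child", "parent"))
  tab <- utils::read.delim(path, header = header,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("DAG table needs two columns", call. = FALSE)
  names(tab)[1:2] <- c("child", "parent")
  term_dag(tab[1:2])
}

#' @rdname read_dag
#' @param dag A `term_dag`.
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "term_dag"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("child\tparent", con, sep = "\n")
  if (nrow(dag$edges))
    writeLines(paste(dag$edges$child, dag$edges$parent, sep = "\t"),
               con, sep = "\n")
  invisible(path)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# leaves-first order: nodes sorted by height (longest path to a leaf
# through child edges), ties broken by term id for determinism
bottom_up_order <- function(dag) {
  height <- stats::setNames(integer(length(dag$nodes)), dag$nodes)
  children_of <- split(dag$edges$child, dag$edges$parent)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (p in names(children_of)) {
      h <- max(height[children_of[[p]]]) + 1L
      if (h > height[[p]]) { height[[p]] <- h; changed <- TRUE }
    }
  }
  names(sort(height))  # stable: sort() on equal heights keeps name order
}

#' Collapse redundant significant terms over a DAG
#'
#' Applies the parent/child redundancy rule to a set of significant
#' terms: for each significant parent, consider its significant direct
#' children whose memberships (restricted to the measured universe)
#' overlap the parent's with Jaccard at or above `overlap_threshold`. If
#' exactly one such child exists, the more specific child is kept and the
#' parent dropped; if two or more sibling children qualify, the more
#' general parent is kept and those children dropped. Terms with no
#' qualifying significant relatives are retained. The rule is applied
#' leaves-first and repeated to a fixed point, so multi-level chains
#' resolve deterministically.
#'
#' @param significant Character vector of significant term ids.
#' @param dag A `term_dag`. Terms absent from the DAG (e.g. pathway ids)
#'   are standalone and always retained.
#' @param sets A `gene_set_collection` giving term memberships; every
#'   significant term must be known to the DAG or the collection.
#' @param overlap_threshold Jaccard threshold in (0, 1] defining "a
#'   similar group of genes".
#' @return List with `retained` (character vector, input order) and
#'   `drop_log` (data frame: `dropped_id`, `kept_id`, `rule`, `jaccard`).
#' @export
collapse_significant_terms <- function(significant, dag, sets,
                                       overlap_threshold = 0.7) {
  stopifnot(inherits(dag, "term_dag"),
            inherits(sets, "gene_set_collection"),
            overlap_threshold > 0, overlap_threshold <= 1)
  significant <- unique(as.character(significant))
  unknown <- setdiff(significant, c(dag$nodes, names(sets$sets)))
  if (length(unknown))
    stop("unknown term id: ", unknown[1L], call. = FALSE)
  retained <- significant
  members <- sets$sets
  children_of <- split(dag$edges$child, dag$edges$parent)
  order_all <- bottom_up_order(dag)
  log_rows <- list()
  repeat {
    dropped_this_pass <- FALSE
    for (p in order_all[order_all %in% retained]) {
      if (!p %in% retained) next
      kids <- intersect(children_of[[p]], retained)
      if (!length(kids)) next
      jac <- vapply(kids, function(ch)
        jaccard(members[[p]], members[[ch]]), 0)
      qual <- kids[!is.na(jac) & jac >= overlap_threshold]
      if (length(qual) == 1L) {
        retained <- setdiff(retained, p)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(dropped_id = p, kept_id = qual,
                     rule = "child_over_parent",
                     jaccard = jac[[qual]], stringsAsFactors = FALSE)
        dropped_this_pass <- TRUE
      } else if (length(qual) >= 2L) {
        retained <- setdiff(retained, qual)
        for (ch in sort(qual))
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(dropped_id = ch, kept_id = p,
                       rule = "parent_over_siblings",
                       jaccard = jac[[ch]], stringsAsFactors = FALSE)
        dropped_this_pass <- TRUE
      }
    }
    if (!dropped_this_pass) break
  }
  drop_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(dropped_id = character(), kept_id = character(),
               rule = character(), jaccard = numeric(),
               stringsAsFactors = FALSE)
  list(retained = significant[significant %in% retained],
       drop_log = drop_log)
}
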