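#' Prior knowledge network
#'
#' A PKN is a signed directed graph of molecular interactions together with
#' the experimental roles of its nodes: stimuli (ligands applied in the
#' design), inhibited nodes (targets of small-molecule inhibitors), measured
#' nodes (read out by the assay). Nodes with no role are intermediates.
#'
#' @param edges data.frame with columns `source` (character), `sign`
#'   (+1/-1 integer) and `target` (character). Duplicate rows are collapsed.
#' @param nodes optional character vector of node names; defaults to the
#'   union of edge endpoints. Isolated nodes may be added here.
#' @param stimuli,inhibited,measured character vectors of node names.
#' @return an object of class `cfl_pkn`.
#' @export
cfl_pkn <- function(edges, nodes = NULL, stimuli = character(),
                    inhibited = character(), measured = character()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "sign", "target") %in% names(edges)))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge sign must be +1 or -1", call. = FALSE)
    }
    if (any(edges$source == "" | edges$target == "")) {
      stop("empty node name in edge list", call. = FALSE)
    }
    edges <- unique(edges[, c("source", "sign", "target")])
    edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), sign = integer(),
                        target = character(), stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(nodes, edges$source, edges$target,
                             stimuli, inhibited, measured)))
  bad <- setdiff(c(stimuli, inhibited, measured), all_nodes)
  if (length(bad)) stop("role assigned to unknown node(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(nodes = all_nodes, edges = edges,
                 stimuli = sort(unique(stimuli)),
                 inhibited = sort(unique(inhibited)),
                 measured = sort(unique(measured))),
            class = "cfl_pkn")
}

#' @export
print.cfl_pkn <- function(x, ...) {
  cat(sprintf("cFL prior knowledge network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  stimuli:   %s\n", paste(x$stimuli, collapse = ", ")))
  cat(sprintf("  inhibited: %s\n", paste(x$inhibited, collapse = ", ")))
  cat(sprintf("  measured:  %s\n", paste(x$measured, collapse = ", ")))
  inter <- pkn_intermediates(x)
  if (length(inter)) cat(sprintf("  intermediate: %s\n", paste(inter, collapse = ", ")))
  invisible(x)
}

#' Designated and intermediate nodes of a PKN
#'
#' Designated nodes are those carrying at least one experimental role
#' (stimulus, inhibited or measured); intermediates carry none.
#'
#' @param pkn a `cfl_pkn`.
#' @return character vector of node names.
#' @export
pkn_designated <- function(pkn) {
  sort(unique(c(pkn$stimuli, pkn$inhibited, pkn$measured)))
}

#' @rdname pkn_designated
#' @export
pkn_intermediates <- function(pkn) {
  setdiff(pkn$nodes, pkn_designated(pkn))
}

#' Assign experimental roles from a dataset
#'
#' Flags each PKN node as stimulus, inhibited and/or measured according to
#' the dataset's treatment, inhibitor and value columns; every other node
#' becomes an intermediate. Dataset columns that name no PKN node are an
#' error: the design must be interpretable on the network.
#'
#' @param pkn a `cfl_pkn`.
#' @param dataset a `cfl_dataset` (see [read_midas()]).
#' @return the PKN with roles replaced by the dataset's.
#' @export
designate_roles <- function(pkn, dataset) {
  stopifnot(inherits(pkn, "cfl_pkn"), inherits(dataset, "cfl_dataset"))
  cols <- c(colnames(dataset$stimuli), colnames(dataset$inhibitors),
            colnames(dataset$obs))
  missing <- setdiff(cols, pkn$nodes)
  if (length(missing)) {
    stop("dataset columns with no matching PKN node: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfl_pkn(pkn$edges, nodes = pkn$nodes,
          stimuli = colnames(dataset$stimuli),
          inhibited = colnames(dataset$inhibitors),
          measured = colnames(dataset$obs))
}

# nodes lying on a directed cycle (including self-loops); used to keep
# compression conservative in cyclic regions
.on_cycle <- function(pkn) {
  n <- length(pkn$nodes)
  if (n == 0 || nrow(pkn$edges) == 0) return(character())
  adj <- matrix(FALSE, n, n, dimnames = list(pkn$nodes, pkn$nodes))
  adj[cbind(pkn$edges$source, pkn$edges$target)] <- TRUE
  reach <- adj
  for (i in seq_len(n)) {        # Floyd-Warshall style transitive closure
    reach <- reach | (reach %*% adj > 0)
  }
  pkn$nodes[diag(reach)]
}

#' Compress a PKN against its experimental design
#'
#' Removes intermediate nodes that can be bypassed without changing the
#' logic relating designated nodes: an intermediate with a single incoming
#' edge or a single outgoing edge is spliced out, each (upstream,
#' downstream) pair being replaced by a direct edge whose sign is the
#' product of the two signs. Intermediates with two or more incoming and
#' two or more outgoing edges are retained, as are intermediates lying on a
#' directed cycle (conservative choice) and multi-input intermediates whose
#' single outgoing edge is inhibitory (negating an OR of inputs does not
#' distribute over the splice). Intermediates with no inputs or no
#' outputs are dropped outright (no basal activity, so they carry no
#' signal). Self-loops created by splicing are discarded. The process
#' iterates to a fixed point.
#'
#' @param pkn a `cfl_pkn` with roles designated.
#' @return the compressed `cfl_pkn`.
#' @export
compress <- function(pkn) {
  stopifnot(inherits(pkn, "cfl_pkn"))
  repeat {
    edges <- pkn$edges
    inter <- pkn_intermediates(pkn)
    cyc <- .on_cycle(pkn)
    changed <- FALSE
    for (nd in inter) {
      ins <- edges[edges$target == nd, , drop = FALSE]
      outs <- edges[edges$source == nd, , drop = FALSE]
      if (nrow(ins) == 0 || nrow(outs) == 0) {
        # dead end or unreachable source: contributes nothing
        edges <- edges[edges$source != nd & edges$target != nd, , drop = FALSE]
        changed <- TRUE
        break
      }
      if (nd %in% cyc) next
      if (nrow(ins) > 1 && nrow(outs) > 1) next
      # a multi-input node feeding a single inhibitory edge computes
      # NOT(OR(inputs)), which does not distribute over the splice
      if (nrow(ins) > 1 && any(outs$sign == -1L)) next
      spliced <- merge(ins[, c("source", "sign")],
                       outs[, c("sign", "target")], by = NULL)
      new_edges <- data.frame(source = spliced$source,
                              sign = spliced$sign.x * spliced$sign.y,
                              target = spliced$target,
                              stringsAsFactors = FALSE)
      new_edges <- new_edges[new_edges$source != new_edges$target, , drop = FALSE]
      edges <- rbind(edges[edges$source != nd & edges$target != nd, , drop = FALSE],
                     new_edges)
      changed <- TRUE
      break
    }
    if (!changed) break
    keep_nodes <- unique(c(pkn_designated(pkn), edges$source, edges$target))
    pkn <- cfl_pkn(edges, nodes = keep_nodes, stimuli = pkn$stimuli,
                   inhibited = pkn$inhibited, measured = pkn$measured)
  }
  pkn
}
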