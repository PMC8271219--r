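#' Construct a signed regulatory network topology
#'
#' A `network_topology` is a signed directed graph: an ordered set of node
#' names and a set of regulatory edges, each labelled activation or
#' inhibition.  Self-loops are allowed; at most one edge may connect a given
#' (source, target) pair.
#'
#' @param edges data.frame with columns `source`, `target` (character) and
#'   `sign` (`"activation"` or `"inhibition"`).
#' @param nodes optional character vector of node names.  Defaults to the
#'   nodes in order of first appearance in `edges` (sources before targets
#'   within a row).  Extra names declare isolated nodes.
#' @return An object of class `network_topology` with elements `nodes`
#'   (character) and `edges` (data.frame).
#' @export
#' @examples
#' topo <- network_topology(data.frame(
#'   source = c("A", "B"), target = c("B", "A"),
#'   sign = c("inhibition", "inhibition")
#' ))
network_topology <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    if (!all(c("source", "target", "sign") %in% names(edges))) {
      stop("`edges` needs columns source, target, sign", call. = FALSE)
    }
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.character(edges$sign)
    bad <- !edges$sign %in% c("activation", "inhibition")
    if (any(bad)) {
      stop("unknown edge sign: ", paste(unique(edges$sign[bad]), collapse = ", "),
           call. = FALSE)
    }
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key)) {
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    }
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  seen <- unique(as.vector(t(as.matrix(edges[, c("source", "target")]))))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("node names must be unique", call. = FALSE)
    missing_nodes <- setdiff(seen, nodes)
    if (length(missing_nodes)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(missing_nodes, collapse = ", "), call. = FALSE)
    }
  }
  if (length(nodes) == 0) stop("topology has no nodes", call. = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "network_topology")
}

#' Read a topology from a whitespace-separated edge list
#'
#' The "topo" dialect has one edge per line: `SOURCE TARGET TYPE` with
#' `TYPE` 1 for activation and 2 for inhibition.  A header line
#' (`Source Target Type`, any case) is optional and skipped.
#'
#' @param path path to the edge-list file.
#' @return A [network_topology()].
#' @seealso [write_topology()], [default_topology()]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) &&
      grepl("^source\\s+target\\s+type$", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop("no edges in topology file: ", path, call. = FALSE)
  rows <- strsplit(lines, "\\s+")
  bad <- vapply(rows, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed topo line ", lineno[which(bad)[1]], ": ",
         lines[which(bad)[1]], call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  type <- suppressWarnings(as.integer(mat[, 3]))
  bad <- is.na(type) | !type %in% c(1L, 2L)
  if (any(bad)) {
    stop("unknown sign code on line ", lineno[which(bad)[1]], ": ",
         lines[which(bad)[1]], " (expected 1 = activation, 2 = inhibition)",
         call. = FALSE)
  }
  key <- paste(mat[, 1], mat[, 2])
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate edge on line ", lineno[i], ": ", lines[i], call. = FALSE)
  }
  network_topology(data.frame(
    source = mat[, 1], target = mat[, 2],
    sign = c("activation", "inhibition")[type],
    stringsAsFactors = FALSE
  ))
}

#' Write a topology in the topo edge-list dialect
#'
#' Round-trips exactly with [read_topology()] (up to isolated nodes, which
#' the format cannot express).
#'
#' @param topology a [network_topology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "network_topology"))
  e <- topology$edges
  type <- ifelse(e$sign == "activation", 1L, 2L)
  writeLines(c("Source Target Type", paste(e$source, e$target, type)), path)
  invisible(path)
}

#' The bundled EMT-estrogen-receptor network
#'
#' Five nodes — ERa66 (full-length estrogen receptor alpha), ERa36 (its
#' truncated variant), the EMT transcription factors SLUG and ZEB1, and the
#' epithelial microRNA family miR200 — connected by ten signed edges:
#' ERa66 self-activates and represses ERa36 and SLUG; SLUG and ZEB1 repress
#' ERa66; ERa36 activates ZEB1; ZEB1 self-activates and forms a mutual
#' inhibition loop with miR200; SLUG represses miR200.
#'
#' @return A [network_topology()] with 5 nodes and 10 edges.
#' @export
default_topology <- function() {
  read_topology(system.file("extdata", "emt_er_network.topo",
                            package = "emtamr", mustWork = TRUE))
}

#' @export
print.network_topology <- function(x, ...) {
  cat("network_topology:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$sign == "activation", "->", "-|")
    cat(paste0("  ", x$edges$source, " ", arrow, " ", x$edges$target),
        sep = "\n")
  }
  invisible(x)
}

# Integer node index lookup used across the package.
node_index <- function(topology, names) {
  idx <- match(names, topology$nodes)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
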