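#' Evidence policy for interaction filtering
#'
#' Whitelist and blacklist of interaction-detection method terms. The
#' defaults encode the evidence classes retained for the network — affinity
#' purification of complexes, protein-fragment complementation,
#' reconstituted complexes in vitro, Far Western blotting and biochemical
#' activity — and the classes removed: high-throughput screens,
#' colocalization, cofractionation and two-hybrid. Matching is
#' case-insensitive substring, which covers both free-text method names and
#' controlled-vocabulary codes listed verbatim.
#'
#' @param whitelist,blacklist character vectors of method terms; they must be
#'   disjoint.
#' @return An `evidencePolicy` list.
#' @export
evidencePolicy <- function(
    whitelist = c("affinity purification", "affinity chromatography",
                  "protein-fragment complementation", "complementation assay",
                  "reconstituted complex", "far western",
                  "biochemical activity"),
    blacklist = c("two-hybrid", "two hybrid", "colocalization",
                  "cofractionation", "high throughput", "high-throughput")) {
  if (length(intersect(tolower(whitelist), tolower(blacklist))))
    stop("whitelist and blacklist must be disjoint")
  structure(list(whitelist = tolower(whitelist),
                 blacklist = tolower(blacklist)),
            class = "evidencePolicy")
}

matchesAny <- function(method, terms) {
  m <- tolower(method)
  any(vapply(terms, function(t) grepl(t, m, fixed = TRUE), TRUE))
}

#' Filter interaction records by evidence policy
#'
#' Blacklisted methods are always dropped; only whitelisted methods are kept;
#' methods in neither list are dropped conservatively, with a message naming
#' them for audit.
#'
#' @param records data.frame as returned by [readInteractions()].
#' @param policy an [evidencePolicy()].
#' @return The surviving records.
#' @export
filterInteractions <- function(records, policy = evidencePolicy()) {
  if (!nrow(records)) return(records)
  black <- vapply(records$method, matchesAny, TRUE,
                  terms = policy$blacklist)
  white <- vapply(records$method, matchesAny, TRUE,
                  terms = policy$whitelist)
  unlisted <- !black & !white
  if (any(unlisted))
    message("dropping ", sum(unlisted), " record(s) with unlisted method(s): ",
            paste(unique(records$method[unlisted]), collapse = ", "))
  out <- records[white & !black, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the interaction network
#'
#' Nodes are all proteins occurring in the (already filtered) records plus
#' any extra nodes in `classMap`; parallel records collapse to one undirected
#' edge carrying the list of supporting records; self-loops are retained but
#' flagged. Each node is annotated with its family's emergence epoch (or
#' `"unknown"`) and functional class. The result is independent of record
#' order.
#'
#' @param records filtered interaction records.
#' @param emergence optional [EmergenceMatrix-class] for epoch annotation
#'   (node ids are matched against its family names).
#' @param classMap optional named character vector, protein -> functional
#'   class (`accessory`, `CLASP`, `hub`).
#' @return A [PINGraph-class].
#' @export
buildNetwork <- function(records, emergence = NULL,
                         classMap = character()) {
  nodes <- sort(unique(c(records$proteinA, records$proteinB,
                         names(classMap))))
  a <- pmin(records$proteinA, records$proteinB)
  b <- pmax(records$proteinA, records$proteinB)
  key <- paste(a, b, sep = "\r")
  o <- order(key, method = "radix")
  recLab <- paste0(records$method, "[", records$sourceDb, "]")
  edges <- data.frame(a = a[o], b = b[o], lab = recLab[o])
  byEdge <- split(edges$lab, paste(edges$a, edges$b, sep = "\r"))
  ekeys <- sort(names(byEdge), method = "radix")
  ea <- sub("\r.*$", "", ekeys)
  eb <- sub("^.*\r", "", ekeys)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(ekeys))
    g <- igraph::add_edges(g, rbind(ea, eb))
  igraph::E(g)$records <- vapply(ekeys, function(k)
    paste(sort(byEdge[[k]]), collapse = ";"), "")
  igraph::E(g)$nRecords <- vapply(ekeys, function(k)
    length(byEdge[[k]]), 0L)
  igraph::E(g)$selfLoop <- ea == eb
  ep <- rep("unknown", length(nodes))
  if (!is.null(emergence)) {
    hit <- match(nodes, names(epochs(emergence)))
    ep[!is.na(hit)] <- epochs(emergence)[hit[!is.na(hit)]]
  }
  igraph::V(g)$epoch <- ep
  cls <- rep("unknown", length(nodes))
  hit <- match(nodes, names(classMap))
  cls[!is.na(hit)] <- unname(classMap[hit[!is.na(hit)]])
  igraph::V(g)$class <- cls
  methods::new("PINGraph", graph = g)
}

#' Export an interaction network
#'
#' GraphML is lossless for nodes, edges and annotations; SIF keeps only the
#' edge list (record lists are lost); edge-TSV writes one row per edge with
#' annotations.
#'
#' @param x a [PINGraph-class].
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(x, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  g <- x@graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(g)
    writeLines(if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(),
               path)
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(proteinA = el[, 1], proteinB = el[, 2],
                     nRecords = if (igraph::ecount(g))
                       igraph::E(g)$nRecords else integer(),
                     records = if (igraph::ecount(g))
                       igraph::E(g)$records else character())
    writeTsvAtomic(df, path)
  }
  invisible(path)
}

#' Import a GraphML network
#'
#' @param path GraphML file written by [exportNetwork()].
#' @return A [PINGraph-class].
#' @export
importNetworkGraphML <- function(path) {
  methods::new("PINGraph", graph = igraph::read_graph(path,
                                                      format = "graphml"))
}
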