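#' Export the trait-trait multi-edge network
#'
#' Combines genetic correlation (GC), phenotypic correlation (PC),
#' pleiotropy, and Mendelian randomization (MR) edges into one multigraph.
#' GC and pleiotropy edges anchor the display: PC and MR edges are emitted
#' only for pairs that also carry a GC or pleiotropy edge. GC/PC edge
#' weights are the absolute coefficients; pleiotropy edges are weighted by
#' VSI; MR edges are directed exposure -> outcome.
#'
#' @param gc data.frame with `trait_i`, `trait_j`, `rg`, `significant`.
#' @param pc data.frame with `trait_i`, `trait_j`, `r`, `significant`.
#' @param vsi data.frame from [detect_pleiotropy()] (`trait_i`, `trait_j`,
#'   `vsi`).
#' @param mr data.frame from [consensus_mr()].
#' @param path optional file path; writes GraphML when it ends in
#'   `.graphml`, else a tab-separated edge list.
#' @return list with `edges` (data.frame: from, to, type, weight,
#'   directed) and `graph` (an igraph object).
#' @export
export_network <- function(gc = NULL, pc = NULL, vsi = NULL, mr = NULL,
                           path = NULL) {
  edges <- list()
  add <- function(from, to, type, weight, directed) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, weight = weight,
      directed = directed, stringsAsFactors = FALSE
    )
  }
  anchor <- character(0)
  pairkey <- function(a, b) {
    apply(cbind(a, b), 1, function(r) paste(sort(r), collapse = "|"))
  }
  if (!is.null(gc) && nrow(gc)) {
    g <- gc[gc$significant, , drop = FALSE]
    if (nrow(g)) {
      add(g$trait_i, g$trait_j, "GC", abs(g$rg), FALSE)
      anchor <- c(anchor, pairkey(g$trait_i, g$trait_j))
    }
  }
  if (!is.null(vsi) && nrow(vsi)) {
    add(vsi$trait_i, vsi$trait_j, "pleiotropy", vsi$vsi, FALSE)
    anchor <- c(anchor, pairkey(vsi$trait_i, vsi$trait_j))
  }
  anchor <- unique(anchor)
  if (!is.null(pc) && nrow(pc)) {
    p <- pc[pc$significant, , drop = FALSE]
    p <- p[pairkey(p$trait_i, p$trait_j) %in% anchor, , drop = FALSE]
    if (nrow(p)) add(p$trait_i, p$trait_j, "PC", abs(p$r), FALSE)
  }
  if (!is.null(mr) && nrow(mr)) {
    m <- mr[mr$consensus_significant, , drop = FALSE]
    m <- m[pairkey(m$exposure, m$outcome) %in% anchor, , drop = FALSE]
    if (nrow(m)) add(m$exposure, m$outcome, "MR", abs(m$ivw_estimate), TRUE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else data.frame(
    from = character(0), to = character(0), type = character(0),
    weight = numeric(0), directed = logical(0)
  )
  graph <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!is.null(path)) {
    if (grepl("\\.graphml$", path)) {
      igraph::write_graph(graph, path, format = "graphml")
    } else {
      utils::write.table(edges, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  }
  list(edges = edges, graph = graph)
}
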