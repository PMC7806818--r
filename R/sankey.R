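# Sankey export of the disease-progression model: one node per
# (state, depth), one link per transition, flow conserved at every
# non-absorbing node.

#' Convert a fitted disease-progression model to a Sankey graph
#'
#' Nodes are (state, depth) pairs: first-line at depth 1, its destinations
#' at depth 2, and so on; DEATH and CONTINUE appear at the depth where they
#' are reached. Link widths carry the transition counts and the branch
#' percentage out of the source state.
#'
#' @param x an `mm_dpm` fit or its `transitions` data.frame.
#' @param stratum stratum label to extract; `NULL` pools all strata by
#'   summing counts (valid because pooled counts equal the sum over
#'   strata).
#' @return object of class `sankey_graph`: `nodes` (`id`, `label`, `state`,
#'   `depth`) and `links` (`source`, `target`, `count`, `pct`).
#' @export
to_sankey <- function(x, stratum = NULL) {
  tab <- if (inherits(x, "mm_dpm")) x$transitions else x
  if (!is.null(stratum)) {
    tab <- tab[tab$stratum == stratum, , drop = FALSE]
  } else if ("stratum" %in% names(tab)) {
    agg <- stats::aggregate(count ~ from + to, data = tab, FUN = sum)
    occ <- tapply(agg$count, agg$from, sum)
    agg$n_at_risk <- as.integer(occ[agg$from])
    agg$probability <- agg$count / agg$n_at_risk
    tab <- agg
  }
  if (nrow(tab) == 0) stopf("no transitions to draw")

  line_depth <- function(state) as.integer(sub("^L", "", state))
  nodes <- data.frame(id = "L1@1", label = "L1", state = "L1", depth = 1L,
                      stringsAsFactors = FALSE)
  links <- list()
  for (src in intersect(JOURNEY_STATES[1:3], unique(tab$from))) {
    d <- line_depth(src)
    rows <- tab[tab$from == src, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      dest <- rows$to[i]
      dd <- d + 1L
      id <- sprintf("%s@%d", dest, dd)
      if (!id %in% nodes$id)
        nodes <- rbind(nodes, data.frame(id = id, label = dest, state = dest,
                                         depth = dd, stringsAsFactors = FALSE))
      links[[length(links) + 1]] <- data.frame(
        source = sprintf("%s@%d", src, d), target = id,
        count = rows$count[i], pct = 100 * rows$probability[i],
        stringsAsFactors = FALSE)
    }
  }
  links <- do.call(rbind, links)
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links), class = "sankey_graph")
}

#' Audit flow conservation of a Sankey graph
#'
#' At every non-absorbing node the inflow must equal the outflow (entrants
#' = movers + deaths + continuers).
#'
#' @param graph a `sankey_graph`.
#' @return `TRUE` invisibly, or an error describing the violated node.
#' @export
check_flow_conservation <- function(graph) {
  for (id in graph$nodes$id[!graph$nodes$state %in% c("DEATH", "CONTINUE")]) {
    inflow <- sum(graph$links$count[graph$links$target == id])
    outflow <- sum(graph$links$count[graph$links$source == id])
    if (inflow > 0 && outflow > 0 && inflow != outflow)
      stopf("flow not conserved at node %s: in %d, out %d", id, inflow, outflow)
  }
  invisible(TRUE)
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat(sprintf("Sankey graph: %d nodes, %d links, %d patients entering\n",
              nrow(x$nodes), nrow(x$links),
              sum(x$links$count[x$links$source == "L1@1"])))
  invisible(x)
}

#' Write a Sankey graph as JSON
#'
#' Emits `{"nodes": [{id,label,depth}...], "links":
#' [{source,target,count,pct}...]}`, consumable by standard Sankey
#' renderers.
#'
#' @param graph a `sankey_graph`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_sankey_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes[c("id", "label", "depth")],
         links = graph$links),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot a disease-progression model as a Sankey-style band diagram
#'
#' Base-graphics rendering: states as stacked rectangles per depth, links
#' as shaded polygons with width proportional to patient counts.
#'
#' @param x an `mm_dpm` fit.
#' @param stratum stratum to draw (`NULL` pools).
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.mm_dpm <- function(x, stratum = NULL, ...) {
  g <- to_sankey(x, stratum)
  nodes <- g$nodes; links <- g$links
  total <- sum(links$count[links$source == "L1@1"])
  nodes$size <- vapply(nodes$id, function(id) {
    max(sum(links$count[links$target == id]),
        sum(links$count[links$source == id]))
  }, numeric(1))
  depths <- sort(unique(nodes$depth))
  # stack nodes within each depth
  nodes$y0 <- NA_real_; nodes$y1 <- NA_real_
  for (d in depths) {
    idx <- which(nodes$depth == d)
    y <- total
    for (i in idx) {
      nodes$y1[i] <- y
      nodes$y0[i] <- y - nodes$size[i]
      y <- y - nodes$size[i] - 0.05 * total
    }
  }
  graphics::plot(NA, xlim = c(min(depths) - 0.2, max(depths) + 0.6),
                 ylim = c(min(nodes$y0, na.rm = TRUE) - 0.05 * total,
                          total * 1.05),
                 axes = FALSE, xlab = "", ylab = "",
                 main = if (is.null(stratum)) "Disease progression" else stratum,
                 ...)
  cols <- c(L1 = "#4e79a7", L2 = "#59a14f", L3 = "#9c755f",
            DEATH = "#e15759", CONTINUE = "#bab0ac")
  # links first
  src_off <- stats::setNames(nodes$y1, nodes$id)
  tgt_off <- stats::setNames(nodes$y1, nodes$id)
  for (i in seq_len(nrow(links))) {
    s <- links$source[i]; t <- links$target[i]; w <- links$count[i]
    sx <- nodes$depth[nodes$id == s] + 0.12
    tx <- nodes$depth[nodes$id == t] - 0.12
    graphics::polygon(c(sx, tx, tx, sx),
                      c(src_off[s], tgt_off[t], tgt_off[t] - w, src_off[s] - w),
                      col = grDevices::adjustcolor("grey60", 0.45), border = NA)
    src_off[s] <- src_off[s] - w
    tgt_off[t] <- tgt_off[t] - w
  }
  for (i in seq_len(nrow(nodes))) {
    graphics::rect(nodes$depth[i] - 0.12, nodes$y0[i],
                   nodes$depth[i] + 0.12, nodes$y1[i],
                   col = cols[nodes$state[i]], border = NA)
    graphics::text(nodes$depth[i], nodes$y1[i] + 0.02 * total,
                   sprintf("%s (n=%d)", nodes$label[i], round(nodes$size[i])),
                   cex = 0.8)
  }
  invisible(g)
}
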