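#' Pairwise Pearson correlations between phosphoproteins of one cell line
#'
#' For every unordered pair of phosphoproteins, correlates the two proteins'
#' measurement vectors formed by concatenating the selected conditions
#' across all time points (default: untreated control plus the six ligand
#' treatments, i.e. 7 conditions x 3 time points = 21 observations per
#' protein). The p-value is the exact t-transform of r with `n_obs - 2`
#' degrees of freedom, two-sided. Inhibitor-combination conditions are
#' excluded: correlation structure under kinase inhibition is a different
#' question from ligand-driven co-variation.
#'
#' @param dataset A [signaling_dataset()].
#' @param cell_line Cell line to analyze.
#' @param conditions Treatment labels to include; default control + all
#'   ligand treatments.
#' @return A tibble of edges: `cell_line`, `protein_a`, `protein_b`
#'   (`a` before `b` in declared protein order), `r`, `p`, `n_obs`, `q`
#'   (`NA` until [storey_qvalues()] is applied via [annotate_significance()]
#'   or manually). Pairs involving a zero-variance vector get `r = NA` and
#'   are excluded from the q-value family.
#' @export
pairwise_correlations <- function(dataset, cell_line, conditions = NULL) {
  stopifnot(inherits(dataset, "signaling_dataset"))
  md <- dataset$metadata
  if (!cell_line %in% md$cell_lines)
    stop_selection("unknown cell line '%s'", cell_line)
  conditions <- conditions %||% c(md$control, md$treatments)
  ph <- dataset$phospho
  ph <- ph[ph$cell_line == cell_line & ph$treatment %in% conditions &
             is.na(ph$inhibitor), , drop = FALSE]
  if (nrow(ph) == 0) stop_selection("no measurements for the requested conditions")
  # fixed observation order: condition-major, time ascending
  ph <- ph |>
    dplyr::arrange(match(.data$treatment, conditions), .data$time_h)
  vectors <- split(ph$value, factor(ph$protein, levels = md$proteins))
  n_obs <- length(conditions) * length(md$time_points)
  bad_len <- vapply(vectors, length, integer(1)) != n_obs
  if (any(bad_len))
    stop_schema("incomplete measurement vector(s) for protein(s): %s",
                paste(names(vectors)[bad_len], collapse = ", "))
  pairs <- utils::combn(md$proteins, 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    va <- vectors[[pairs[1, j]]]
    vb <- vectors[[pairs[2, j]]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      inform(sprintf("zero-variance vector for pair %s-%s: correlation undefined",
                     pairs[1, j], pairs[2, j]))
      return(tibble::tibble(protein_a = pairs[1, j], protein_b = pairs[2, j],
                            r = NA_real_, p = NA_real_, n_obs = n_obs))
    }
    ct <- stats::cor.test(va, vb, method = "pearson", alternative = "two.sided")
    tibble::tibble(protein_a = pairs[1, j], protein_b = pairs[2, j],
                   r = unname(ct$estimate), p = ct$p.value, n_obs = n_obs)
  })
  edges$q <- NA_real_
  dplyr::bind_cols(tibble::tibble(cell_line = cell_line), edges)
}

#' Storey q-values for a family of p-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m * (1 - lambda))` at a fixed `lambda` (default
#' 0.5), clamped into (0, 1], then converts ordered p-values via
#' `q(i) = min_\{j >= i\} pi0 * m * p(j) / j`, so q-values are monotone
#' non-decreasing in p and capped at 1. With `pi0 = 1` this reduces exactly
#' to the Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs passed through).
#' @param lambda Tuning point for the pi0 estimate.
#' @param pi0 Optional override of the estimated null proportion (e.g. `1`
#'   for plain BH).
#' @return Numeric vector of q-values, same order as `p`.
#' @references Storey, J.D. & Tibshirani, R. (2003) Statistical significance
#'   for genomewide studies. PNAS 100, 9440-9445.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(p)
  if (any(pv < 0 | pv > 1)) stop_contract("p-values must lie in [0, 1]")
  if (length(lambda) != 1 || lambda <= 0 || lambda >= 1)
    stop_contract("lambda must be a single value in (0, 1)")
  if (is.null(pi0)) {
    pi0 <- sum(pv > lambda) / (m * (1 - lambda))
    pi0 <- min(1, max(pi0, 1 / (m * (1 - lambda))))
  }
  ord <- order(pv)
  ranked <- pi0 * m * pv[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

#' Tag correlation edges by their significance tier
#'
#' Fills in Storey q-values (per family, defined by the rows passed in) and
#' tags each edge: `q_significant` if the q-value clears `alpha`
#' (significant after multiple-testing adjustment, drawn solid in network
#' figures), `p_only` if only the raw p-value clears `alpha` (dotted), else
#' `none`.
#'
#' @param edges Edge tibble from [pairwise_correlations()]; if `q` is all
#'   `NA` it is computed here with [storey_qvalues()].
#' @param alpha Significance level (default 0.05).
#' @param lambda Passed to [storey_qvalues()].
#' @return The edge tibble with `q` filled and a `tag` column.
#' @export
annotate_significance <- function(edges, alpha = 0.05, lambda = 0.5) {
  stopifnot(all(c("p", "q") %in% names(edges)))
  if (all(is.na(edges$q))) edges$q <- storey_qvalues(edges$p, lambda = lambda)
  edges$tag <- dplyr::case_when(
    !is.na(edges$q) & edges$q <= alpha ~ "q_significant",
    !is.na(edges$p) & edges$p < alpha ~ "p_only",
    TRUE ~ "none")
  edges
}

#' Build a signed treatment-response graph
#'
#' Source nodes (ligands, or inhibitors) are connected to every
#' phosphoprotein with an edge weighted by the mean percent change over
#' untreated control across the three time points; a negative weight
#' (reduction in phosphorylation, rendered red/dashed in figures) carries
#' sign -1. For inhibitor sources the mean is additionally taken over the
#' co-administered ligand treatments.
#'
#' @param dataset A [signaling_dataset()].
#' @param cell_line Cell line to analyze; must have a control condition.
#' @param sources `"ligands"` (default), `"inhibitors"`, or an explicit
#'   character vector of treatment or inhibitor labels.
#' @return An object of class `response_graph`: `nodes` (name, type) and
#'   `edges` (source, protein, weight, sign).
#' @export
build_response_graph <- function(dataset, cell_line, sources = "ligands") {
  stopifnot(inherits(dataset, "signaling_dataset"))
  md <- dataset$metadata
  ph <- dataset$phospho[dataset$phospho$cell_line == cell_line, , drop = FALSE]
  ctrl <- ph[ph$treatment == md$control & is.na(ph$inhibitor), , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop_selection("cell line '%s' has no untreated control condition", cell_line)
  ctrl_lookup <- stats::setNames(ctrl$value, paste(ctrl$protein, ctrl$time_h))
  if (any(ctrl_lookup <= 0))
    stop_contract("control measurements must be positive to define percent change")

  if (identical(sources, "ligands")) {
    source_type <- "ligand"; source_labels <- md$treatments
    rows_for <- function(s) ph[ph$treatment == s & is.na(ph$inhibitor), , drop = FALSE]
  } else if (identical(sources, "inhibitors")) {
    source_type <- "inhibitor"; source_labels <- md$inhibitors
    if (length(source_labels) == 0)
      stop_selection("dataset has no inhibitor conditions")
    rows_for <- function(s) ph[!is.na(ph$inhibitor) & ph$inhibitor == s, , drop = FALSE]
  } else {
    source_type <- "custom"; source_labels <- sources
    rows_for <- function(s) ph[(ph$treatment == s & is.na(ph$inhibitor)) |
                                 (!is.na(ph$inhibitor) & ph$inhibitor == s), ,
                               drop = FALSE]
  }
  edges <- purrr::map_dfr(source_labels, function(s) {
    rows <- rows_for(s)
    if (nrow(rows) == 0)
      stop_selection("no measurements for source '%s' in cell line '%s'", s, cell_line)
    rows$pct <- percent_change(rows$value,
                               ctrl_lookup[paste(rows$protein, rows$time_h)])
    rows |>
      dplyr::group_by(protein = .data$protein) |>
      dplyr::summarise(weight = mean(.data$pct), .groups = "drop") |>
      dplyr::mutate(source = s, sign = ifelse(.data$weight < 0, -1L, 1L)) |>
      dplyr::select("source", "protein", "weight", "sign")
  })
  edges$protein <- as.character(edges$protein)
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = source_labels, type = source_type),
    tibble::tibble(name = md$proteins, type = "protein"))
  structure(list(nodes = nodes, edges = edges, cell_line = cell_line),
            class = "response_graph")
}

#' @export
print.response_graph <- function(x, ...) {
  cat(sprintf("<response_graph> %s: %d source(s) -> %d protein(s), %d edges (%d negative)\n",
              x$cell_line, sum(x$nodes$type != "protein"),
              sum(x$nodes$type == "protein"), nrow(x$edges),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Split a response graph into reduction and activation subgraphs
#'
#' Mirrors the inhibition/activation panel pair of inhibitor-response
#' figures: one graph of edges where phosphorylation fell below control
#' (negative weight) and one where it rose.
#'
#' @param graph A `response_graph`.
#' @return A list with elements `reduction` and `activation`, both
#'   `response_graph`s.
#' @export
split_response_graph <- function(graph) {
  stopifnot(inherits(graph, "response_graph"))
  pick <- function(keep) {
    g <- graph
    g$edges <- graph$edges[keep, , drop = FALSE]
    g
  }
  list(reduction = pick(graph$edges$sign < 0),
       activation = pick(graph$edges$sign >= 0))
}

#' Export a response graph for Cytoscape and other graph tools
#'
#' GraphML output stores `weight`, `sign` and `abs_weight` edge attributes
#' (absolute weight is the conventional edge-thickness variable); SIF output
#' writes the plain interaction file plus a tab-separated edge-attribute
#' table next to it.
#'
#' @param graph A `response_graph`.
#' @param path Output file path (`.graphml`, or `.sif` plus a generated
#'   `*_edges.tsv`).
#' @param format `"graphml"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  stopifnot(inherits(graph, "response_graph"))
  format <- match.arg(format)
  edges <- graph$edges
  if (format == "graphml") {
    if (nrow(edges) == 0) {
      g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = TRUE)
      igraph::V(g)$name <- graph$nodes$name
      igraph::V(g)$type <- graph$nodes$type
    } else {
      g <- igraph::graph_from_data_frame(
        d = data.frame(from = edges$source, to = edges$protein,
                       weight = edges$weight, sign = edges$sign,
                       abs_weight = abs(edges$weight)),
        directed = TRUE, vertices = as.data.frame(graph$nodes))
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- if (nrow(edges) == 0) character() else
      paste(edges$source, "affects", edges$protein)
    writeLines(lines, path)
    attr_path <- sub("\\.sif$", "", path)
    attr_path <- paste0(attr_path, "_edges.tsv")
    readr::write_tsv(tibble::tibble(source = edges$source, target = edges$protein,
                                    weight = edges$weight, sign = edges$sign,
                                    abs_weight = abs(edges$weight)),
                     attr_path)
  }
  invisible(path)
}
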