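make_two_protein_dataset <- function(vals_a, vals_b) {
  treatments <- c("t1", "t2", "t3", "t4", "t5", "t6")
  conds <- tibble::tibble(cell_line = "A",
                          treatment = c("control", treatments),
                          inhibitor = NA_character_)
  grid <- tidyr::expand_grid(conds,
                             tibble::tibble(protein = rep(c("P1", "P2"), each = 3),
                                            time_h = rep(c(0.5, 4, 24), 2)))
  grid$value <- NA_real_
  grid$value[grid$protein == "P1"] <- vals_a
  grid$value[grid$protein == "P2"] <- vals_b
  surv <- dplyr::mutate(conds, survival_pct = c(100, rep(90, 6)))
  signaling_dataset(grid, surv,
                    metadata = list(cell_lines = "A", treatments = treatments,
                                    control = "control", inhibitors = character(),
                                    inhibitor_cell_line = NA_character_,
                                    proteins = c("P1", "P2"),
                                    time_points = c(0.5, 4, 24)))
}

test_that("a protein correlated with its own copy scores r = 1", {
  set.seed(41)
  v <- abs(rnorm(21, 5, 1))
  ds <- make_two_protein_dataset(v, v)
  edges <- pairwise_correlations(ds, "A")
  expect_equal(nrow(edges), 1)
  expect_equal(edges$r, 1, tolerance = 1e-12)
  expect_lt(edges$p, 1e-12)
  expect_equal(edges$n_obs, 21)
})

test_that("eight proteins give exactly 28 edges over 21 observations", {
  ds <- generate_dataset(synthetic_spec(), seed = 18)
  edges <- pairwise_correlations(ds, "line2")
  expect_equal(nrow(edges), choose(8, 2))
  expect_true(all(edges$n_obs == 7 * 3))
  expect_true(all(abs(edges$r) <= 1))
  expect_error(pairwise_correlations(ds, "missing"),
               class = "signalpls_selection_error")
})

test_that("p-values are approximately uniform when proteins are independent", {
  # independent measurement noise only: no latent structure, no planted map
  spec <- synthetic_spec(effect_sd = 0, noise_sd_x = 0.3, replicate_cv = 0,
                         true_beta = rep(0, 24), inhibitors = character(),
                         cell_lines = paste0("L", 1:12))
  ps <- unlist(lapply(1:3, function(s) {
    ds <- generate_dataset(spec, seed = 50 + s)
    unlist(lapply(spec$cell_lines, function(cl) pairwise_correlations(ds, cl)$p))
  }))
  expect_gte(length(ps), 1000)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Storey q-values reduce to Benjamini-Hochberg and stay monotone", {
  set.seed(42)
  p <- c(runif(40), runif(10, 0, 0.01))
  expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, method = "BH"),
               tolerance = 1e-12)
  q <- storey_qvalues(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)])) || all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1 & q >= 0))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-15)) # pi0 <= 1 never inflates BH
  expect_equal(storey_qvalues(rep(1, 10)), rep(1, 10))
  # single test: pi0 clamps and q stays bounded by p
  expect_lte(storey_qvalues(0.04), 0.04)
  expect_error(storey_qvalues(c(0.5, 1.2)), class = "signalpls_contract_error")
})

test_that("significance tags follow the solid/dotted/none semantics", {
  edges <- tibble::tibble(p = c(0.001, 0.03, 0.5), q = c(0.01, 0.2, 0.8))
  tagged <- annotate_significance(edges)
  expect_identical(tagged$tag, c("q_significant", "p_only", "none"))
  # q computed in-place when missing
  edges2 <- tibble::tibble(p = c(0.001, 0.8), q = NA_real_)
  tagged2 <- annotate_significance(edges2)
  expect_false(anyNA(tagged2$q))
})

test_that("response-graph weights average percent change over time points", {
  # flat data: all weights zero
  flat <- make_two_protein_dataset(rep(2, 21), rep(5, 21))
  g0 <- build_response_graph(flat, "A", sources = c("t1", "t2"))
  expect_true(all(g0$edges$weight == 0))
  expect_true(all(g0$edges$sign == 1))
  # a single 3200% spike at one of three time points averages to 1066.67
  va <- rep(2, 21)
  va[4] <- 2 * 33 # t1, first time point of P1
  spike <- make_two_protein_dataset(va, rep(5, 21))
  g1 <- build_response_graph(spike, "A", sources = c("t1"))
  w <- g1$edges$weight[g1$edges$protein == "P1"]
  expect_equal(w, 3200 / 3, tolerance = 1e-9)
  # sign always matches the weight
  ds <- generate_dataset(synthetic_spec(), seed = 19)
  g <- build_response_graph(ds, "line1", "ligands")
  expect_true(all(g$edges$sign == ifelse(g$edges$weight < 0, -1, 1)))
})

test_that("response-graph weights are invariant to rescaling a protein's unit", {
  ds <- generate_dataset(small_spec(), seed = 20)
  g1 <- build_response_graph(ds, "A", "ligands")
  scaled <- ds
  pick <- scaled$phospho$protein == "P2"
  scaled$phospho$value[pick] <- scaled$phospho$value[pick] * 7
  g2 <- build_response_graph(scaled, "A", "ligands")
  expect_equal(g1$edges$weight, g2$edges$weight, tolerance = 1e-12)
})

test_that("inhibitor graphs separate reductions from activations", {
  ds <- generate_dataset(synthetic_spec(), seed = 21)
  g <- build_response_graph(ds, "line1", "inhibitors")
  expect_equal(nrow(g$edges), 5 * 8) # sources x proteins
  halves <- split_response_graph(g)
  expect_true(all(halves$reduction$edges$weight < 0))
  expect_true(all(halves$activation$edges$weight >= 0))
  expect_equal(nrow(halves$reduction$edges) + nrow(halves$activation$edges),
               nrow(g$edges))
  no_ctrl <- select_rows(ds, include_control = FALSE, include_inhibitors = TRUE)
  expect_error(build_response_graph(no_ctrl, "line1", "ligands"),
               class = "signalpls_selection_error")
})

test_that("graph exports round-trip through GraphML and write SIF sidecars", {
  ds <- generate_dataset(synthetic_spec(), seed = 22)
  g <- build_response_graph(ds, "line2", "ligands")
  expect_equal(nrow(g$edges), 6 * 8)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(g$edges))
  el <- igraph::as_data_frame(back, what = "edges")
  key <- function(a, b) paste(a, b)
  expect_setequal(key(el$from, el$to), key(g$edges$source, g$edges$protein))
  expect_equal(sort(el$weight), sort(g$edges$weight), tolerance = 1e-9)
  # SIF plus edge-attribute table
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, format = "sif")
  expect_length(readLines(sif), nrow(g$edges))
  attr_file <- paste0(sub("\\.sif$", "", sif), "_edges.tsv")
  expect_true(file.exists(attr_file))
  expect_equal(nrow(readr::read_tsv(attr_file, show_col_types = FALSE)),
               nrow(g$edges))
  # empty graph still exports a valid file
  g$edges <- g$edges[0, ]
  empty_path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, empty_path)
  expect_equal(igraph::ecount(igraph::read_graph(empty_path, format = "graphml")), 0)
})
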