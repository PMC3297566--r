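test_that("leader clustering founds and assigns clusters as specified", {
  base <- ref_backbone(3)
  # all frames identical -> one cluster led by frame 0
  same <- make_traj(rep(list(base), 5))
  cl <- leader_cluster(same, seq_len(nrow(base)))
  expect_equal(length(cl$leaders), 1)
  expect_equal(cl$leaders, 0L)
  expect_true(all(cl$assignments == 0L))
  # single frame
  single <- make_traj(list(base))
  expect_equal(glance(leader_cluster(single, 1:9))$n_clusters, 1)
  expect_equal(leader_cluster(single, 1:9)$assignments, 0L)
  expect_error(leader_cluster(single, integer(0)), "non-empty")
})

test_that("two alternating rigid conformers give exactly two clusters", {
  a <- ref_backbone(3)
  b <- a + cbind(rep(0, 9), rep(0, 9), 5 * rep(c(1, -1, 1), 3))
  # verify the planted separation with an exhaustive pairwise RMSD matrix
  frames <- rep(list(a, b), 5)
  n <- length(frames)
  rm_mat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    rm_mat[i, j] <- quat_rmsd(frames[[i]], frames[[j]])
  }
  expect_true(all(rm_mat[seq(1, n, 2), seq(2, n, 2)] > 2))
  expect_true(all(rm_mat[seq(1, n, 2), seq(1, n, 2)] < 1e-8))
  cl <- leader_cluster(make_traj(frames), 1:9, cutoff = 2)
  expect_equal(length(cl$leaders), 2)
  expect_equal(cl$assignments, rep(c(0L, 1L), 5))
})

test_that("every frame lies within the cutoff of its assigned leader", {
  set.seed(21)
  frames <- purrr::map(1:40, function(i) {
    ref_backbone(3) + matrix(rnorm(27, sd = runif(1, 0.1, 2)), 9, 3)
  })
  traj <- make_traj(frames)
  cl <- leader_cluster(traj, 1:9, cutoff = 1.5)
  for (f in seq_along(frames)) {
    leader_frame <- frames[[cl$leaders[cl$assignments[f] + 1] + 1]]
    expect_lte(superpose(frames[[f]], leader_frame)$rmsd, 1.5 + 1e-12)
    # each leader is assigned to itself
  }
  expect_equal(cl$assignments[cl$leaders + 1] + 0L,
               seq_along(cl$leaders) - 1L)
})

test_that("microstate codes concatenate contact bits with the cluster id", {
  recs <- tibble::tibble(
    name = c("-7:331", "-7:332", "-4:331"), kind = "ionic",
    occupancy = c(1, 1, 0),
    formed = list(c(TRUE, FALSE), c(TRUE, FALSE), c(FALSE, FALSE)))
  cl <- structure(list(cutoff = 2, leaders = c(0L, 1L),
                       assignments = c(2L, 0L)),
                  class = "leader_clustering")
  codes <- encode_microstates(recs, cl)
  expect_equal(codes, c("110|2", "000|0"))
  expect_equal(contact_pattern(codes), c("110", "000"))
  cl$assignments <- 0L
  expect_error(encode_microstates(recs, cl), "frames")
})

test_that("recovered contact patterns match the generator ground truth at low noise", {
  sim <- gen_markov_trajectory(traj_generator_spec(n_frames = 4000,
                                                   jitter_sigma = 0.15,
                                                   seed = 3))
  recs <- contact_timeseries(sim$trajectory, toy_contact_specs())
  cl <- leader_cluster(sim$trajectory,
                       select_backbone(sim$trajectory, chain = "P"))
  codes <- encode_microstates(recs, cl)
  agreement <- mean(contact_pattern(codes) == sim$patterns)
  expect_gte(agreement, 0.99)
  # conformation clusters track the hidden mode backbone
  expect_equal(length(cl$leaders), 3)
})

test_that("the conformation-space network counts nodes and edges exactly", {
  csn <- build_csn(c("A", "A", "B", "A"))
  expect_equal(sort(csn$nodes$population, decreasing = TRUE), c(3L, 1L))
  expect_equal(csn$nodes$population[csn$nodes$code == "A"], 3L)
  e <- function(f, t) csn$edges$count[csn$edges$from == f & csn$edges$to == t]
  expect_equal(e("A", "A"), 1L)
  expect_equal(e("A", "B"), 1L)
  expect_equal(e("B", "A"), 1L)
  expect_equal(sum(csn$nodes$population), csn$total_frames)
  two <- build_csn(list(c("A", "B"), c("A", "B")))
  expect_equal(two$edges$count[two$edges$from == "A" & two$edges$to == "B"],
               2L)
  expect_false(any(two$edges$from == "B"))
  expect_error(build_csn(list(character(0))), "non-empty")
})

test_that("per-node outflow equals population minus final-frame appearances", {
  sim_codes <- list(c("A", "B", "A", "A", "C"), c("C", "B", "B"))
  csn <- build_csn(sim_codes)
  finals <- table(vapply(sim_codes, function(s) s[length(s)], ""))
  for (i in seq_len(nrow(csn$nodes))) {
    code <- csn$nodes$code[i]
    outflow <- sum(csn$edges$count[csn$edges$from == code])
    final_n <- if (code %in% names(finals)) as.integer(finals[[code]]) else 0L
    expect_equal(outflow, csn$nodes$population[i] - final_n)
  }
})

test_that("transition frequencies of a synthetic chain match the generator", {
  tm <- matrix(c(0.95, 0.05, 0.08, 0.92), 2, 2, byrow = TRUE)
  spec <- traj_generator_spec(
    transition_matrix = tm,
    state_contact_map = list("-7:331", "-4:331"),
    n_frames = 30000, doorway = FALSE, seed = 5)
  sim <- gen_markov_trajectory(spec)
  codes <- as.character(sim$states)
  csn <- build_csn(codes)
  # row-normalised edge counts vs the generator matrix, 3 conditional-
  # multinomial standard errors
  pi_hat <- markov_stationary(tm)
  for (i in 1:2) {
    out <- csn$edges[csn$edges$from == as.character(i), ]
    n_i <- sum(out$count)
    for (j in 1:2) {
      p_hat <- out$count[out$to == as.character(j)] / n_i
      se <- sqrt(tm[i, j] * (1 - tm[i, j]) / ((spec$n_frames - 1) * pi_hat[i]))
      expect_lt(abs(p_hat - tm[i, j]), 3 * se)
    }
  }
})

test_that("gradient clustering finds population local maxima as attractors", {
  # linear chain with populations 5-3-1: one basin, attractor the 5-node
  chain <- build_csn(c(rep("a", 5), rep("b", 3), "c",
                       "b", "a", "a", "a", "a"))
  # constructed so edges are a-b and b-c only
  expect_true(all(chain$edges$from != "c" | chain$edges$to != "a"))
  basins <- gradient_cluster(chain)
  expect_equal(nrow(basins), 1)
  expect_equal(basins$basin, "a")
  expect_setequal(basins$members[[1]], c("a", "b", "c"))
  # all populations equal: every node its own basin
  flat <- build_csn(c("x", "y", "z", "x", "y", "z"))
  expect_equal(nrow(gradient_cluster(flat)), 3)
})

test_that("two population peaks joined by their tails give two basins", {
  nodes <- tibble::tibble(
    code = c("p5", "p3", "p1", "q4", "q2"),
    population = c(5L, 3L, 1L, 4L, 2L),
    pattern = "x")
  edges <- tibble::tibble(
    from = c("p5", "p3", "p1", "q4"),
    to = c("p3", "p1", "q2", "q2"),
    count = 1L)
  csn <- structure(list(nodes = nodes, edges = edges, total_frames = 15L,
                        n_runs = 1L), class = "csn")
  basins <- gradient_cluster(csn)
  expect_setequal(basins$basin, c("p5", "q4"))
  adj <- matrix(0, 5, 5, dimnames = list(nodes$code, nodes$code))
  for (k in seq_len(nrow(edges))) {
    adj[edges$from[k], edges$to[k]] <- 1
    adj[edges$to[k], edges$from[k]] <- 1
  }
  oracle <- brute_basins(setNames(nodes$population, nodes$code), adj)
  got <- setNames(rep(basins$basin, lengths(basins$members)),
                  unlist(basins$members))
  expect_equal(got[names(oracle)], oracle)
})

test_that("gradient clustering matches exhaustive steepest ascent on random networks", {
  for (seed in 1:100) {
    csn <- random_csn(n_nodes = sample(3:12, 1), seed = seed)
    basins <- gradient_cluster(csn)
    adj <- matrix(0, nrow(csn$nodes), nrow(csn$nodes),
                  dimnames = list(csn$nodes$code, csn$nodes$code))
    ed <- csn$edges[csn$edges$from != csn$edges$to, ]
    for (k in seq_len(nrow(ed))) {
      adj[ed$from[k], ed$to[k]] <- 1
      adj[ed$to[k], ed$from[k]] <- 1
    }
    oracle <- brute_basins(setNames(csn$nodes$population, csn$nodes$code),
                           adj)
    got <- setNames(rep(basins$basin, lengths(basins$members)),
                    unlist(basins$members))
    expect_equal(got[names(oracle)], oracle,
                 label = sprintf("seed %d assignment", seed))
    # attractors are exactly the population-local-maxima
    is_max <- vapply(csn$nodes$code, function(u) {
      nb <- colnames(adj)[adj[u, ] > 0]
      length(nb) == 0 ||
        csn$nodes$population[csn$nodes$code == u] >=
          max(csn$nodes$population[csn$nodes$code %in% nb])
    }, TRUE)
    expect_setequal(basins$basin, csn$nodes$code[is_max])
  }
})

test_that("coarse graining reports hand-countable basin transition weights", {
  # 6-node fixture with three basins {A,a1}, {B,b1}, {C,c1}; the only
  # inter-basin traffic runs along a1-b1 and b1-c1
  nodes <- tibble::tibble(
    code = c("A", "a1", "B", "b1", "C", "c1"),
    population = c(12L, 3L, 10L, 3L, 7L, 2L),
    pattern = c("100", "100", "001", "001", "110", "110"))
  edges <- tibble::tibble(
    from = c("A", "A", "a1", "a1", "b1", "b1", "B", "B", "b1", "c1",
             "c1", "C", "C"),
    to = c("A", "a1", "A", "b1", "a1", "B", "b1", "B", "c1", "b1",
           "C", "c1", "C"),
    count = c(10L, 2L, 2L, 1L, 1L, 2L, 2L, 8L, 1L, 1L, 1L, 1L, 6L))
  csn <- structure(list(nodes = nodes, edges = edges,
                        total_frames = sum(nodes$population), n_runs = 1L),
                   class = "csn")
  basins <- gradient_cluster(csn)
  expect_setequal(basins$basin, c("A", "B", "C"))
  coarse <- coarse_grain(csn, basins)
  expect_equal(sum(coarse$nodes$fraction), 1, tolerance = 1e-12)
  total <- sum(edges$count)  # 38 transitions in all
  get_w <- function(f, t) {
    w <- coarse$edges$probability[coarse$edges$from == f &
                                    coarse$edges$to == t]
    if (length(w) == 0) 0 else w
  }
  expect_equal(get_w("A", "B"), 1 / total)   # a1 -> b1
  expect_equal(get_w("B", "A"), 1 / total)   # b1 -> a1
  expect_equal(get_w("B", "C"), 1 / total)   # b1 -> c1
  expect_equal(get_w("C", "B"), 1 / total)   # c1 -> b1
  expect_equal(get_w("A", "C"), 0)
  # single basin: one node, fraction 1, no inter-basin edges
  one <- build_csn(c("u", "u", "v"))
  cb <- coarse_grain(one, gradient_cluster(one))
  expect_equal(nrow(cb$nodes), 1)
  expect_equal(cb$nodes$fraction, 1)
  expect_equal(nrow(cb$edges), 0)
  # non-partition input rejected
  bad <- gradient_cluster(one)
  bad$members[[1]] <- bad$members[[1]][-1]
  expect_error(coarse_grain(one, bad), "partition")
})

test_that("coarse-grained populations track generator mode probabilities", {
  spec <- traj_generator_spec(n_frames = 30000, seed = 9)
  sim <- gen_markov_trajectory(spec)
  recs <- contact_timeseries(sim$trajectory, toy_contact_specs())
  cl <- leader_cluster(sim$trajectory,
                       select_backbone(sim$trajectory, chain = "P"))
  csn <- build_csn(encode_microstates(recs, cl))
  basins <- gradient_cluster(csn)
  coarse <- coarse_grain(csn, basins)
  p_exp <- expanded_transition_matrix(spec)
  pi_exp <- markov_stationary(p_exp)
  k <- spec$n_states
  # the doorway nodes drain into the largest mode's basin; compare each
  # basin's population against the stationary probability of its states
  modes_pat <- vapply(spec$state_contact_map, pdzmodes:::pattern_of, "")
  big <- which.max(pi_exp[seq_len(k)])
  for (m in seq_len(k)) {
    expected <- pi_exp[m] + if (m == big) sum(pi_exp[(k + 1):(2 * k)]) else 0
    states_m <- c(m, if (m == big) (k + 1):(2 * k))
    se <- markov_indicator_se(p_exp, states_m, spec$n_frames)
    got <- coarse$nodes$fraction[coarse$nodes$label == modes_pat[m]]
    expect_equal(length(got), 1)
    expect_lt(abs(got - expected), 3 * se)
  }
})

test_that("network export writes GraphML and TSV side files", {
  csn <- build_csn(c("A", "B", "A", "A"))
  dir <- withr::local_tempdir()
  files <- write_network(csn, file.path(dir, "csn"))
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(files[1], format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))
  basins <- gradient_cluster(csn)
  bp <- write_basins(basins, file.path(dir, "basins.tsv"))
  tab <- readr::read_tsv(bp, show_col_types = FALSE)
  expect_setequal(tab$code, c("A", "B"))
})
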