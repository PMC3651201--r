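test_that("a planted exact copy is recovered at rank 1 with rmsddm 0", {
  inst <- make_instance(4, seed = 101, jitter = 0, n_decoys = 20)
  hits <- search_template(inst$pool)
  expect_true(attr(hits, "searched"))
  expect_gte(nrow(hits), 1)
  expect_equal(hits$rmsddm[1], 0, tolerance = 1e-9)
  top <- hits$mapping[[1]]
  truth <- inst$planted$truth
  expect_equal(top$resno, truth$resno)
  expect_equal(top$chain, truth$chain)
})

test_that("a jittered planted copy is rank 1 and rmsddm matches direct evaluation", {
  for (seed in c(7, 19, 31)) {
    inst <- make_instance(4, seed = seed, jitter = 0.1, n_decoys = 30)
    hits <- search_template(inst$pool)
    top <- hits$mapping[[1]]
    expect_equal(top$resno, inst$planted$truth$resno)
    d_S <- as.matrix(dist(as.matrix(top[, c("x", "y", "z")])))
    expect_equal(hits$rmsddm[1], rmsddm(inst$template$dmat, d_S),
                 tolerance = 1e-10)
  }
})

test_that("a pairwise distance beyond the edge screen excludes the planted mapping", {
  tpl <- generate_template(3, seed = 55, ec = "1.1.1.1", site_id = "TH-0")
  pl <- plant_in_decoy(tpl, jitter_sigma = 0, n_decoys = 0, seed = 56,
                       target_id = "th")
  # displace the first planted residue along the axis to its neighbour by
  # +2.0 A (beyond the 1.5 A screen)
  res <- pl$target$residues
  truth_rows <- match(pl$truth$resno, res$resno)
  v <- c(res$ca_x[truth_rows[2]] - res$ca_x[truth_rows[1]],
         res$ca_y[truth_rows[2]] - res$ca_y[truth_rows[1]],
         res$ca_z[truth_rows[2]] - res$ca_z[truth_rows[1]])
  v <- v / sqrt(sum(v^2))
  res$ca_x[truth_rows[1]] <- res$ca_x[truth_rows[1]] - 2.0 * v[1]
  res$ca_y[truth_rows[1]] <- res$ca_y[truth_rows[1]] - 2.0 * v[2]
  res$ca_z[truth_rows[1]] <- res$ca_z[truth_rows[1]] - 2.0 * v[3]
  tgt <- new_target_structure("th", res, pl$target$het_atoms)
  hits <- search_template(build_candidate_pool(tgt, tpl))
  sig <- vapply(hits$mapping, function(mp) paste(mp$resno, collapse = ","),
                character(1))
  expect_false(paste(pl$truth$resno, collapse = ",") %in% sig)
})

test_that("unsearchable templates report no-search, distinct from zero hits", {
  cat <- parse_site_table(I("site_id\tec\tresidues\n1un-0\t1.1.1.1\tHIS A 1"))
  st <- make_structure(tibble::tibble(code = "HIS", chain = "A",
                                      resno = 1, x = 0, y = 0, z = 0))
  pool <- build_candidate_pool(st, cat$template[[1]])
  hits <- search_template(pool)
  expect_false(attr(hits, "searched"))
  expect_equal(nrow(hits), 0)
})

test_that("brute force enumerates injective canonical assignments", {
  # distinct types with pools (3, 2): 6 assignments evaluated
  st <- make_structure(tibble::tibble(
    code = c("ALA", "ALA", "ALA", "ARG", "ARG"), chain = "A", resno = 1:5,
    x = c(0, 20, 40, 4, 24), y = 0, z = 0))
  cat <- parse_site_table(I(paste(
    "site_id\tec\tresidues", "1bf-0\t1.1.1.1\tALA A 1; ARG A 4",
    sep = "\n")))
  tpl <- resolve_centroids(cat$template[[1]],
                           make_structure(tibble::tibble(
                             code = c("ALA", "ARG"), chain = "A",
                             resno = c(1, 4), x = c(0, 4), y = 0, z = 0),
                             id = "1bf"))
  pool <- build_candidate_pool(st, tpl)
  est <- predict_comparisons(tpl, pool)
  expect_equal(est$n_candidates, 6)
  cfg <- search_config(edge_threshold = 1000)
  hits <- enumerate_matches_bruteforce(pool, cfg)
  expect_equal(nrow(hits), 6)

  # duplicate-type template ALA,ALA with 4 pooled ALA: C(4,2) = 6, not 12
  st2 <- make_structure(tibble::tibble(
    code = rep("ALA", 4), chain = "A", resno = 1:4,
    x = c(0, 5, 10, 15), y = 0, z = 0))
  tpl2 <- resolve_centroids(
    parse_site_table(I(paste("site_id\tec\tresidues",
                             "1dp-0\t1.1.1.1\tALA A 1; ALA A 2",
                             sep = "\n")))$template[[1]],
    make_structure(tibble::tibble(code = c("ALA", "ALA"), chain = "A",
                                  resno = 1:2, x = c(0, 5), y = 0, z = 0),
                   id = "1dp"))
  pool2 <- build_candidate_pool(st2, tpl2)
  expect_equal(predict_comparisons(tpl2, pool2)$n_candidates, 6)
  hits2 <- enumerate_matches_bruteforce(pool2, cfg)
  expect_equal(nrow(hits2), 6)
  # every mapping is in canonical (increasing residue) order
  for (mp in hits2$mapping) expect_true(mp$resno[1] < mp$resno[2])
})

test_that("search equals the brute-force oracle when pruning is disabled", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:30) {
    n_T <- sample(2:5, 1)
    inst <- make_instance(n_T, seed = 1000 + rep,
                          jitter = runif(1, 0, 0.3),
                          n_decoys = sample(5:12, 1))
    cfg <- search_config(p_max = 1e7)
    got <- search_template(inst$pool, cfg)
    oracle <- enumerate_matches_bruteforce(inst$pool, cfg)
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(hit_signature(got), hit_signature(oracle))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 30)
})

test_that("every returned edge passes the screen and pruning is monotone", {
  for (rep in 1:10) {
    inst <- make_instance(3, seed = 2000 + rep, jitter = 0.4,
                          n_decoys = 15)
    hits <- search_template(inst$pool)
    thr <- search_config()$edge_threshold
    for (mp in hits$mapping) {
      d_S <- as.matrix(dist(as.matrix(mp[, c("x", "y", "z")])))
      dev <- abs(inst$template$dmat - d_S)
      expect_lte(max(dev[upper.tri(dev)]), thr)
    }
    # enlarging p_max never removes a returned match
    h1 <- search_template(inst$pool, search_config(p_max = 1))
    h100 <- search_template(inst$pool, search_config(p_max = 100))
    expect_true(all(hit_signature(h1) %in% hit_signature(h100)))
  }
})

test_that("results are invariant to pool input ordering", {
  inst <- make_instance(4, seed = 77, jitter = 0.2, n_decoys = 20)
  res <- inst$planted$target$residues
  shuffled <- new_target_structure("inst",
                                   res[sample(nrow(res)), ],
                                   inst$planted$target$het_atoms)
  pool2 <- build_candidate_pool(shuffled, inst$template)
  expect_equal(hit_signature(search_template(pool2)),
               hit_signature(search_template(inst$pool)))
})

test_that("comparison-count predictions match the instrumented search", {
  # uniform case, distinct types, thresholds disabled: observed == full
  # when pruning is off, and enum cost is n_T * N^n_T
  set.seed(9)
  n_T <- 3; N <- 6
  codes <- c("ALA", "CYS", "HIS")
  spec <- tibble::tibble(
    code = rep(codes, each = N), chain = "A",
    resno = 1:(n_T * N),
    x = runif(n_T * N, 0, 30), y = runif(n_T * N, 0, 30),
    z = runif(n_T * N, 0, 30))
  st <- make_structure(spec)
  tpl <- resolve_centroids(
    parse_site_table(I(paste(
      "site_id\tec\tresidues",
      sprintf("1sc-0\t1.1.1.1\t%s", paste(sprintf("%s A %d", codes,
                                                  seq(1, N * n_T, N)),
                                          collapse = "; ")),
      sep = "\n")))$template[[1]],
    st)
  pool <- build_candidate_pool(st, tpl)
  est <- predict_comparisons(tpl, pool, p_max = Inf)
  expect_equal(est$enum_cost, n_T * N^n_T)
  expect_equal(est$full_comparisons, N^2 + N^3)
  expect_equal(est$pruned_comparisons, est$full_comparisons)

  cfg <- search_config(edge_threshold = 1e6, p_max = 1e9)
  hits <- search_template(pool, cfg)
  expect_equal(attr(hits, "n_comparisons"), est$full_comparisons)

  # with pruning the prediction still tracks the instrumented count
  est50 <- predict_comparisons(tpl, pool, p_max = 20)
  hits50 <- search_template(pool, search_config(edge_threshold = 1e6,
                                                p_max = 20))
  expect_equal(attr(hits50, "n_comparisons"), est50$pruned_comparisons)
  expect_lte(est50$pruned_comparisons, est$full_comparisons)
  expect_lte(attr(hits50, "n_comparisons"), est$full_comparisons)

  # n_T = 2: a single buildup step, all predictions coincide
  tpl2 <- resolve_centroids(
    parse_site_table(I(paste("site_id\tec\tresidues",
                             "1s2-0\t1.1.1.1\tALA A 1; CYS A 7",
                             sep = "\n")))$template[[1]], st)
  pool2 <- build_candidate_pool(st, tpl2)
  est2 <- predict_comparisons(tpl2, pool2, p_max = 3)
  expect_equal(est2$pruned_comparisons, est2$full_comparisons)
})
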