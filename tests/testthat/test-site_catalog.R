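catalog_text <- function(rows) {
  paste(c("site_id\tec\tresidues", rows), collapse = "\n")
}

test_that("parsing canonicalizes residue order and keeps 1-residue sites", {
  cat <- parse_site_table(I(catalog_text(c(
    "1abc-0\t3.4.21.4\tHIS A 57; ASP A 102; SER A 195",
    "1abc-1\t1.1.1.1\tGLU B 35"
  ))))
  expect_equal(nrow(cat), 2)
  tpl <- cat$template[[1]]
  expect_equal(tpl$n, 3)
  expect_equal(tpl$residues$code, c("ASP", "HIS", "SER"))
  expect_true(cat$searchable[1])
  expect_false(cat$searchable[2])
  expect_equal(cat$n_residues[2], 1)

  # canonical order is invariant under input row order
  cat2 <- parse_site_table(I(catalog_text(
    "1abc-0\t3.4.21.4\tSER A 195; HIS A 57; ASP A 102")))
  expect_equal(cat2$template[[1]]$residues, tpl$residues)
})

test_that("malformed rows, empty residue lists, duplicate ids error", {
  expect_error(parse_site_table(I(catalog_text("1abc-0\t1.1.1.1\t"))),
               "empty residue")
  expect_error(parse_site_table(I(catalog_text("1abc-0\t1.1.1.1\tHIS A"))),
               "row 1")
  expect_error(parse_site_table(I(catalog_text(c(
    "1abc-0\t1.1.1.1\tHIS A 57", "1abc-0\t1.1.1.1\tASP A 1")))),
    "duplicate site_id")
})

test_that("centroid resolution maps CSE to CYS C-alpha and cofactors to their rule atom", {
  cat <- parse_site_table(I(catalog_text(
    "1sel-0\t1.8.4.11\tCSE A 10; HIS A 20; HEM A 300")))
  tpl <- cat$template[[1]]
  cse <- tpl$residues[tpl$residues$raw_code == "CSE", ]
  expect_equal(cse$code, "CYS")
  expect_equal(cse$category, "nonstandard")
  expect_equal(cse$centroid_atom, "CA")

  st <- make_structure(tibble::tibble(
    code = c("CSE", "HIS"), chain = "A", resno = c(10, 20),
    x = c(0, 6), y = 0, z = 0),
    het = tibble::tibble(resid = "HEM", chain = "A", resno = 300L,
                         elety = "FE", x = 3, y = 4, z = 0))
  resolved <- resolve_centroids(tpl, st)
  expect_true(resolved$resolved)
  cys <- resolved$residues[resolved$residues$raw_code == "CSE", ]
  expect_equal(c(cys$x, cys$y, cys$z), c(0, 0, 0))
  fe <- resolved$residues[resolved$residues$raw_code == "HEM", ]
  expect_equal(c(fe$x, fe$y, fe$z), c(3, 4, 0))
  expect_equal(dim(resolved$dmat), c(3, 3))
})

test_that("an 8-residue site yields a 28-element distance matrix", {
  set.seed(4)
  codes <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE")
  st <- make_structure(tibble::tibble(
    code = codes, chain = "A", resno = 1:8,
    x = runif(8, 0, 15), y = runif(8, 0, 15), z = runif(8, 0, 15)))
  cat <- parse_site_table(I(catalog_text(paste0(
    "1aa6-1\t3.40.50.720\t",
    paste(sprintf("%s A %d", codes, 1:8), collapse = "; ")))))
  tpl <- resolve_centroids(cat$template[[1]], st)
  expect_equal(tpl$n, 8)
  expect_equal(sum(upper.tri(tpl$dmat)), 28)
  expect_true(all(tpl$dmat[upper.tri(tpl$dmat)] > 0))
  expect_equal(tpl$dmat, t(tpl$dmat))
  expect_equal(diag(tpl$dmat), rep(0, 8))
})

test_that("resolution errors name missing residues and unknown codes", {
  st <- make_structure(tibble::tibble(code = "HIS", chain = "A",
                                      resno = 20, x = 0, y = 0, z = 0))
  cat <- parse_site_table(I(catalog_text(
    "1abc-0\t1.1.1.1\tHIS A 20; ASP A 99")))
  expect_error(resolve_centroids(cat$template[[1]], st), "ASP A99")

  cat2 <- parse_site_table(I(catalog_text(
    "1abc-0\t1.1.1.1\tHIS A 20; XXX A 300")))
  expect_error(resolve_centroids(cat2$template[[1]], st), "XXX")
})

test_that("template distance matrix is invariant under rigid transformation", {
  for (seed in 1:5) {
    tpl <- generate_template(5, seed = seed)
    xyz <- as.matrix(tpl$residues[, c("x", "y", "z")])
    moved <- rigid_transform(xyz, seed = seed + 50)
    res2 <- tpl$residues
    res2$x <- moved[, 1]; res2$y <- moved[, 2]; res2$z <- moved[, 3]
    tpl2 <- sitematch:::new_site_template(tpl$site_id, tpl$ec, res2)
    expect_equal(tpl2$dmat, tpl$dmat, tolerance = 1e-8)
  }
})

test_that("multichain sites split into cx plus per-chain sites", {
  st <- make_structure(tibble::tibble(
    code = c("ASP", "GLU", "HIS", "SER"),
    chain = c("A", "A", "B", "B"), resno = c(1, 2, 3, 4),
    x = c(0, 4, 30, 34), y = 0, z = 0))
  cat <- parse_site_table(I(catalog_text(
    "1xyz-0\t1.1.1.1\tASP A 1; GLU A 2; HIS B 3; SER B 4")))
  tpl <- resolve_centroids(cat$template[[1]], st)
  parts <- split_multimeric(tpl)
  expect_equal(length(parts), 3)
  ids <- vapply(parts, function(p) p$site_id, character(1))
  expect_setequal(ids, c("1xyz-0cx", "1xyz-0A", "1xyz-0B"))
  cx <- parts[[which(ids == "1xyz-0cx")]]
  expect_equal(cx$residues[, c("code", "chain", "resno")],
               tpl$residues[, c("code", "chain", "resno")])
  a <- parts[[which(ids == "1xyz-0A")]]
  b <- parts[[which(ids == "1xyz-0B")]]
  expect_equal(sort(c(a$residues$resno, b$residues$resno)),
               sort(tpl$residues$resno))
})

test_that("compact sites are unchanged and distant clusters split as mfm", {
  st <- make_structure(tibble::tibble(
    code = c("ASP", "GLU", "HIS"), chain = "A", resno = 1:3,
    x = c(0, 6, 12), y = 0, z = 0))
  cat <- parse_site_table(I(catalog_text(
    "1cmp-0\t1.1.1.1\tASP A 1; GLU A 2; HIS A 3")))
  tpl <- resolve_centroids(cat$template[[1]], st)
  expect_equal(length(split_multimeric(tpl)), 1)
  expect_identical(split_multimeric(tpl)[[1]]$site_id, "1cmp-0")

  # two 3-residue clusters 30 A apart on one chain -> mfm + 2 cluster sites
  st2 <- make_structure(tibble::tibble(
    code = c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY"),
    chain = "A", resno = 1:6,
    x = c(0, 4, 2, 30, 34, 32), y = c(0, 0, 3, 0, 0, 3), z = 0))
  cat2 <- parse_site_table(I(catalog_text(paste0(
    "1mfm-0\t2.2.2.2\t",
    "ALA A 1; CYS A 2; ASP A 3; GLU A 4; PHE A 5; GLY A 6"))))
  tpl2 <- resolve_centroids(cat2$template[[1]], st2)
  parts <- split_multimeric(tpl2)
  ids <- vapply(parts, function(p) p$site_id, character(1))
  expect_equal(length(parts), 3)
  expect_true("1mfm-0mfm" %in% ids)
  cluster_sizes <- sort(vapply(parts[ids != "1mfm-0mfm"],
                               function(p) p$n, integer(1)))
  expect_equal(cluster_sizes, c(3L, 3L))
  expect_true(all(vapply(parts[ids != "1mfm-0mfm"],
                         function(p) max(p$dmat) <= 20, logical(1))))
})

test_that("substitution matrices admit only count- and EC-matched homologs", {
  tpl <- generate_template(3, seed = 9, ec = "1.2.3.4", site_id = "FAM-0")
  codes <- tpl$residues$code

  # identical homolog: identity-only matrix
  hom_same <- tibble::tibble(
    member_id = "m1", parent_site_id = "FAM-0", ec = "1.2.3.4",
    residues = list(tibble::tibble(raw_code = codes, chain = "A",
                                   resno = 1:3, insert = "")))
  m <- build_substitution_matrix(tpl, hom_same)
  expect_equal(unclass(m)[1:20, 1:20], diag(20L), ignore_attr = TRUE)
  expect_equal(attr(m, "n_substitutions"), 0)
  expect_equal(attr(m, "n_admitted"), 1L)

  # one ASP->GLU difference, admitted, recorded symmetrically
  codes2 <- codes
  swap_at <- 1
  codes2[swap_at] <- if (codes[swap_at] == "ASP") "GLU" else "ASP"
  hom_sub <- hom_same
  hom_sub$residues <- list(tibble::tibble(raw_code = codes2, chain = "A",
                                          resno = 1:3, insert = ""))
  m2 <- build_substitution_matrix(tpl, hom_sub)
  expect_equal(unclass(m2)[codes[swap_at], codes2[swap_at]], 1L)
  expect_equal(unclass(m2)[codes2[swap_at], codes[swap_at]], 1L)
  expect_equal(attr(m2, "n_substitutions"), 1)

  # wrong residue count or wrong EC -> skipped
  hom_bad <- dplyr::bind_rows(
    tibble::tibble(member_id = "m3", parent_site_id = "FAM-0",
                   ec = "1.2.3.4",
                   residues = list(tibble::tibble(
                     raw_code = codes[1:2], chain = "A", resno = 1:2,
                     insert = ""))),
    tibble::tibble(member_id = "m4", parent_site_id = "FAM-0",
                   ec = "9.9.9.9",
                   residues = list(tibble::tibble(
                     raw_code = codes2, chain = "A", resno = 1:3,
                     insert = ""))))
  m3 <- build_substitution_matrix(tpl, hom_bad)
  expect_equal(attr(m3, "n_admitted"), 0L)
  expect_equal(attr(m3, "n_skipped"), 2L)
  expect_equal(unclass(m3)[1:20, 1:20], diag(20L), ignore_attr = TRUE)
})

test_that("every substitution matrix is symmetric with unit diagonal and ion wildcard", {
  for (seed in 1:6) {
    tpl <- generate_template(4, seed = seed, ec = "3.1.1.1",
                             site_id = "S-0")
    hom <- generate_homologs(tpl, sub_prob = 0.5, n_members = 4,
                             seed = seed)
    m <- build_substitution_matrix(tpl, hom)
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_equal(unname(diag(unclass(m))), rep(1L, 20))
    expect_true(attr(m, "ion_wildcard"))
    expect_equal(length(attr(m, "ion_codes")), 22)
  }
})

test_that("substitution summaries aggregate by OR and histogram counts", {
  tpls <- lapply(1:3, function(i) {
    generate_template(3, seed = 20 + i, ec = "1.1.1.1",
                      site_id = paste0("T", i, "-0"))
  })
  homs <- list(
    generate_homologs(tpls[[1]], sub_prob = 0, n_members = 2, seed = 1),
    generate_homologs(tpls[[2]], sub_prob = 1, n_members = 1, seed = 2),
    generate_homologs(tpls[[3]], sub_prob = 1, n_members = 2, seed = 3)
  )
  mats <- Map(build_substitution_matrix, tpls, homs)
  counts <- vapply(mats, function(m) attr(m, "n_substitutions"),
                   numeric(1))
  summ <- summarize_substitutions(mats)
  expect_equal(sort(summ$counts$n_substitutions), sort(as.integer(counts)))
  expect_equal(sum(summ$histogram$n_templates), 3)
  # aggregate is the OR: any pair present in a member matrix is present
  for (m in mats) {
    expect_true(all(summ$aggregate[unclass(m) == 1] == 1))
  }
  # all-identity matrices aggregate to identity with an all-zero histogram
  id_mats <- lapply(tpls, build_substitution_matrix)
  s2 <- summarize_substitutions(id_mats)
  expect_equal(s2$aggregate, diag(20L), ignore_attr = TRUE)
  expect_equal(s2$histogram$n_substitutions, 0L)
  expect_equal(s2$histogram$n_templates, 3L)
})
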