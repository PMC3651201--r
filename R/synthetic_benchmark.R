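# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Idealized backbone around a C-alpha: N at 1.46 A, carbonyl C at 1.52 A,
# N-CA-C angle ~111 degrees, random orientation. Exists solely so the
# backbone-RMSD descriptor is exercisable on synthetic structures.
ideal_backbone <- function(ca) {
  R <- random_rotation()
  n_dir <- R %*% c(1, 0, 0)
  c_dir <- R %*% c(cos(111 * pi / 180), sin(111 * pi / 180), 0)
  list(n = as.numeric(ca + 1.46 * n_dir), c = as.numeric(ca + 1.52 * c_dir))
}

#' Generate a random catalytic-site template
#'
#' Residue codes are drawn from the 20 standard codes (optionally one
#' position becomes an ion); centroid coordinates are rejection-sampled in
#' a 9 Angstrom ball with minimum pairwise separation 3.5 Angstrom and
#' maximum diameter 18 Angstrom (safely below the 20 Angstrom multimeric
#' flag). An idealized backbone is built around every amino-acid centroid.
#' Fully deterministic given the seed.
#'
#' @param n_T Residue count, 2..15.
#' @param seed Integer seed.
#' @param ec EC string assigned to the site (synthetic label space).
#' @param site_id Site identifier.
#' @param ion_prob Probability that one position is an ion.
#' @param ions Ion codes to draw from.
#' @return A resolved `site_template`.
#' @export
generate_template <- function(n_T, seed, ec = "1.1.1.1",
                              site_id = "SYN0-0", ion_prob = 0,
                              ions = default_ions()) {
  if (n_T < 2 || n_T > 15) stop("template size must be in 2..15")
  with_seed(seed, {
    pts <- matrix(NA_real_, n_T, 3)
    pts[1, ] <- 0
    for (i in seq_len(n_T)[-1]) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        p <- runif(3, -9, 9)
        if (sum(p^2) > 81) next
        d <- sqrt(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - p)^2))
        if (min(d) < 3.5) next
        if (max(d) > 18) next
        pts[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place template residue ", i,
                        " under geometry constraints")
    }
    codes <- sample(standard_residues(), n_T, replace = TRUE)
    category <- rep("standard", n_T)
    atom <- rep("CA", n_T)
    if (ion_prob > 0 && runif(1) < ion_prob) {
      i <- sample(n_T, 1)
      codes[i] <- sample(ions, 1)
      category[i] <- "ion"
      atom[i] <- codes[i]
    }
    res <- tibble::tibble(
      raw_code = codes, code = codes, category = category,
      chain = "A", resno = seq_len(n_T) * 10L, insert = "",
      centroid_atom = atom,
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
      ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
      c_x = NA_real_, c_y = NA_real_, c_z = NA_real_
    )
    for (i in seq_len(n_T)) {
      if (category[i] != "standard") next
      bb <- ideal_backbone(pts[i, ])
      res$ca_x[i] <- pts[i, 1]; res$ca_y[i] <- pts[i, 2]
      res$ca_z[i] <- pts[i, 3]
      res$n_x[i] <- bb$n[1]; res$n_y[i] <- bb$n[2]; res$n_z[i] <- bb$n[3]
      res$c_x[i] <- bb$c[1]; res$c_y[i] <- bb$c[2]; res$c_z[i] <- bb$c[3]
    }
    new_site_template(site_id, ec, res)
  })
}

#' Plant a (jittered) template copy in a decoy structure
#'
#' The template's atoms are rigid-body rotated and translated into a decoy
#' box, perturbed by isotropic per-coordinate Gaussian noise, and
#' surrounded by decoy residues with uniform random codes and idealized
#' random-orientation backbones, scattered with a 3.0 Angstrom clash
#' floor. Ground truth (which target residues realize each template
#' position) is recorded.
#'
#' @param template A resolved `site_template`.
#' @param jitter_sigma Per-coordinate noise SD in Angstrom.
#' @param n_decoys Number of decoy residues.
#' @param seed Integer seed.
#' @param target_id Structure identifier.
#' @param box Cubic box edge in Angstrom.
#' @param clash Minimum centroid separation in Angstrom.
#' @return List: `target` (a `target_structure`), `truth` (tibble
#'   `position`, `chain`, `resno`), `jitter_sigma`.
#' @export
plant_in_decoy <- function(template, jitter_sigma = 0, n_decoys = 30,
                           seed = 1, target_id = "target", box = 40,
                           clash = 3.0) {
  stopifnot(jitter_sigma >= 0, inherits(template, "site_template"),
            template$resolved)
  with_seed(seed, {
    R <- random_rotation()
    shift <- runif(3, 0.35 * box, 0.65 * box)
    txf <- function(xyz) {
      if (anyNA(xyz)) return(xyz)
      as.numeric(R %*% xyz + shift + rnorm(3, sd = jitter_sigma))
    }
    tres <- template$residues
    n <- nrow(tres)
    planted <- vector("list", n)
    het <- list()
    for (i in seq_len(n)) {
      ca <- txf(c(tres$x[i], tres$y[i], tres$z[i]))
      if (tres$category[i] %in% c("standard", "nonstandard")) {
        nn <- txf(c(tres$n_x[i], tres$n_y[i], tres$n_z[i]))
        cc <- txf(c(tres$c_x[i], tres$c_y[i], tres$c_z[i]))
        planted[[i]] <- tibble::tibble(
          chain = "A", resno = i, insert = "", resid = tres$raw_code[i],
          n_x = nn[1], n_y = nn[2], n_z = nn[3],
          ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
          c_x = cc[1], c_y = cc[2], c_z = cc[3], has_backbone = TRUE)
      } else {
        het[[length(het) + 1]] <- tibble::tibble(
          resid = tres$raw_code[i], chain = "A", resno = 500L + i,
          elety = tres$centroid_atom[i], x = ca[1], y = ca[2], z = ca[3])
        planted[[i]] <- tibble::tibble(
          chain = "A", resno = 500L + i, insert = "",
          resid = tres$raw_code[i],
          n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
          ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
          c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
          has_backbone = FALSE)
      }
    }
    planted_res <- dplyr::bind_rows(planted[tres$category %in%
                                              c("standard", "nonstandard")])
    placed <- rbind(
      as.matrix(planted_res[, c("ca_x", "ca_y", "ca_z")]),
      if (length(het)) as.matrix(dplyr::bind_rows(het)[, c("x", "y", "z")])
    )
    decoys <- list()
    for (j in seq_len(n_decoys)) {
      for (try in seq_len(5000)) {
        p <- runif(3, 0, box)
        if (nrow(placed) > 0 &&
            min(colSums((t(placed) - p)^2)) < clash^2) next
        bb <- ideal_backbone(p)
        decoys[[j]] <- tibble::tibble(
          chain = "A", resno = 100L + j, insert = "",
          resid = sample(standard_residues(), 1),
          n_x = bb$n[1], n_y = bb$n[2], n_z = bb$n[3],
          ca_x = p[1], ca_y = p[2], ca_z = p[3],
          c_x = bb$c[1], c_y = bb$c[2], c_z = bb$c[3],
          has_backbone = TRUE)
        placed <- rbind(placed, p)
        break
      }
      if (length(decoys) < j) stop("could not place decoy ", j)
    }
    residues <- dplyr::bind_rows(c(list(planted_res), decoys)) |>
      dplyr::arrange(.data$chain, .data$resno)
    target <- new_target_structure(target_id, residues,
                                   if (length(het)) dplyr::bind_rows(het)
                                   else tibble::tibble(
                                     resid = character(0),
                                     chain = character(0),
                                     resno = integer(0),
                                     elety = character(0),
                                     x = numeric(0), y = numeric(0),
                                     z = numeric(0)))
    truth <- tibble::tibble(
      position = seq_len(n),
      chain = "A",
      resno = purrr::map_int(planted, ~ .x$resno[1])
    )
    list(target = target, truth = truth, jitter_sigma = jitter_sigma)
  })
}

#' Generate homolog site entries for a template family
#'
#' Members copy the parent's residue list (in the parent's canonical
#' order) with position-wise substitutions at rate `sub_prob`; optional
#' fractions of members get a mismatched EC number or an altered residue
#' count, to exercise the two admission criteria of
#' [build_substitution_matrix()].
#'
#' @param template Parent `site_template`.
#' @param sub_prob Per-position substitution probability in `[0, 1]`.
#' @param n_members Number of homolog entries.
#' @param seed Integer seed.
#' @param frac_bad_ec Fraction of members given a non-matching EC.
#' @param frac_bad_count Fraction of members with one residue dropped.
#' @return Homolog tibble in the [parse_homolog_table()] layout (with a
#'   `residues` list-column).
#' @export
generate_homologs <- function(template, sub_prob = 0.1, n_members = 3,
                              seed = 1, frac_bad_ec = 0,
                              frac_bad_count = 0) {
  stopifnot(sub_prob >= 0, sub_prob <= 1)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_members), function(m) {
      res <- template$residues
      std <- res$category %in% c("standard", "nonstandard")
      codes <- res$code
      for (i in which(std)) {
        if (runif(1) < sub_prob) {
          codes[i] <- sample(setdiff(standard_residues(), codes[i]), 1)
        }
      }
      ec <- template$ec
      if (runif(1) < frac_bad_ec) ec <- paste0(ec, ".x")
      keep <- rep(TRUE, nrow(res))
      if (runif(1) < frac_bad_count && sum(std) > 1) {
        keep[sample(which(std), 1)] <- FALSE
      }
      tibble::tibble(
        member_id = sprintf("%s-m%02d", template$site_id, m),
        parent_site_id = template$site_id,
        ec = ec,
        residues = list(tibble::tibble(
          raw_code = codes[keep], chain = res$chain[keep],
          resno = res$resno[keep], insert = res$insert[keep]))
      )
    })
  })
}

#' Benchmark specification
#'
#' Study conditions of the synthetic benchmark: a small template library
#' with sizes concentrated on 2-4 residues and a tail to 15 (echoing the
#' size distribution of curated catalytic-site libraries), targets with one
#' planted, jittered true site each, uniform-code decoy residues, and
#' homolog families for substitution derivation. The seed fully determines
#' the output.
#'
#' @param n_families Number of template families.
#' @param sizes,size_probs Template size support and probabilities.
#' @param jitter_max Planted-site jitter SD is drawn uniformly from
#'   `[0, jitter_max]` Angstrom per family.
#' @param n_decoys Decoy residues per target.
#' @param box Target box edge in Angstrom.
#' @param sub_prob Homolog substitution rate.
#' @param n_homologs Homolog members per family.
#' @param ion_prob Probability a template carries one ion position.
#' @param seed Integer seed.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_families = 40,
                           sizes = c(2:8, 10, 12, 15),
                           size_probs = c(0.20, 0.28, 0.26, 0.10, 0.06,
                                          0.04, 0.02, 0.02, 0.01, 0.01),
                           jitter_max = 1.0, n_decoys = 40, box = 40,
                           sub_prob = 0.1, n_homologs = 3, ion_prob = 0.1,
                           seed = 1) {
  stopifnot(length(sizes) == length(size_probs), n_families >= 2,
            jitter_max >= 0)
  structure(list(n_families = n_families, sizes = sizes,
                 size_probs = size_probs / sum(size_probs),
                 jitter_max = jitter_max, n_decoys = n_decoys, box = box,
                 sub_prob = sub_prob, n_homologs = n_homologs,
                 ion_prob = ion_prob, seed = seed),
            class = "benchmark_spec")
}

#' Generate a seeded synthetic benchmark
#'
#' Builds the full benchmark dataset: one template per family (each with a
#' unique synthetic EC number), one target per family with the family's
#' site planted under a family-specific jitter, homolog entries, and
#' per-family substitution matrices. Reproducible from the spec's seed.
#'
#' @param spec A [benchmark_spec()].
#' @return List: `spec`, `catalog` (tibble: `site_id`, `family_id`, `ec`,
#'   `n_residues`, `template` list-column, `subs` list-column),
#'   `targets` (list of `plant_in_decoy()` results plus `target_ec`),
#'   `homologs` (tibble).
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, {
    fam_seed <- sample.int(2^30, spec$n_families)
    n_sizes <- sample(spec$sizes, spec$n_families, replace = TRUE,
                      prob = spec$size_probs)
    jitters <- runif(spec$n_families, 0, spec$jitter_max)
  })
  rows <- list()
  targets <- list()
  homolog_rows <- list()
  for (i in seq_len(spec$n_families)) {
    fam <- sprintf("F%03d", i)
    ec <- sprintf("%d.%d.%d.%d", 1 + (i - 1) %% 6, 1 + (i - 1) %% 9,
                  1 + (i - 1) %% 20, i)
    tpl <- generate_template(n_sizes[i], seed = fam_seed[i], ec = ec,
                             site_id = paste0(fam, "-0"),
                             ion_prob = spec$ion_prob)
    hom <- generate_homologs(tpl, sub_prob = spec$sub_prob,
                             n_members = spec$n_homologs,
                             seed = fam_seed[i] + 1)
    subs <- build_substitution_matrix(tpl, hom)
    planted <- plant_in_decoy(tpl, jitter_sigma = jitters[i],
                              n_decoys = spec$n_decoys,
                              seed = fam_seed[i] + 2,
                              target_id = paste0(fam, "-t"),
                              box = spec$box)
    planted$target_ec <- ec
    planted$family_id <- fam
    rows[[i]] <- tibble::tibble(site_id = tpl$site_id, family_id = fam,
                                ec = ec, n_residues = tpl$n,
                                template = list(tpl), subs = list(subs))
    targets[[i]] <- planted
    homolog_rows[[i]] <- hom
  }
  list(spec = spec, catalog = dplyr::bind_rows(rows), targets = targets,
       homologs = dplyr::bind_rows(homolog_rows))
}

#' Export a template catalog / homolog set in the TSV dialects
#'
#' @param catalog Catalog tibble with `site_id`, `ec` and a `template`
#'   list-column.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_catalog_tsv <- function(catalog, file) {
  tab <- tibble::tibble(
    site_id = catalog$site_id,
    ec = catalog$ec,
    residues = purrr::map_chr(catalog$template, function(t) {
      paste(sprintf("%s %s %d%s", t$residues$raw_code, t$residues$chain,
                    t$residues$resno, t$residues$insert), collapse = "; ")
    })
  )
  readr::write_tsv(tab, file)
  invisible(file)
}

#' @rdname write_catalog_tsv
#' @param homologs Homolog tibble from [generate_homologs()].
#' @export
write_homologs_tsv <- function(homologs, file) {
  tab <- tibble::tibble(
    member_id = homologs$member_id,
    parent_site_id = homologs$parent_site_id,
    ec = homologs$ec,
    residues = purrr::map_chr(homologs$residues, function(r) {
      paste(sprintf("%s %s %d%s", r$raw_code, r$chain, r$resno,
                    r$insert %||% ""), collapse = "; ")
    })
  )
  readr::write_tsv(tab, file)
  invisible(file)
}
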