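# domain-architecture parsing, tandem-CBM detection, genome CBM profiles

test_that("architecture strings parse and classify by prefix", {
  a <- parse_architecture("CBM11+CBM11+CBM11+GH51")
  expect_equal(a$tokens, c("CBM11", "CBM11", "CBM11", "GH51"))
  expect_equal(a$classes, c("CBM", "CBM", "CBM", "catalytic"))

  b <- parse_architecture("GH43_16+CBM6")
  expect_equal(b$tokens, c("GH43_16", "CBM6"))
  expect_equal(b$classes, c("catalytic", "CBM"))
  expect_equal(domain_family(b$tokens), c("GH43", "CBM6"))

  c_ <- parse_architecture("SLH+CBM26")
  expect_equal(c_$classes, c("other", "CBM"))

  # GT is not catalytic by default but can be opted in
  expect_equal(parse_architecture("GT2+CBM6")$classes[1], "other")
  expect_equal(parse_architecture("GT2+CBM6",
                                  catalytic = c("GH", "PL", "CE", "AA",
                                                "GT"))$classes[1],
               "catalytic")

  expect_error(parse_architecture(""), "non-empty")
  expect_error(parse_architecture("++"), "empty after parsing")
})

test_that("the three delimiters yield identical tokens", {
  for (s in c("CBM11+GH51", "CBM11|GH51", "CBM11-GH51"))
    expect_equal(parse_architecture(s)$tokens, c("CBM11", "GH51"))
  # hyphen-written tandem runs parse like the paper writes them
  expect_equal(parse_architecture("CBM11-CBM11-CBM11")$tokens,
               rep("CBM11", 3))
  # hyphens inside free-text labels do not split
  expect_equal(parse_architecture("SLH-like+GH13")$tokens,
               c("SLH-like", "GH13"))
})

test_that("tandem runs match a brute-force window scan", {
  a <- parse_architecture("CBM11+CBM11+CBM11+GH51")
  expect_equal(detect_tandem_cbms(a),
               data.frame(start = 0L, length = 3L))
  expect_equal(nrow(detect_tandem_cbms(parse_architecture("GH13"))), 0L)
  b <- parse_architecture("CBM6+GH43_16+CBM6+CBM91")
  expect_equal(detect_tandem_cbms(b),
               data.frame(start = 2L, length = 2L))

  for (raw in random_archs(2000, seed = 99)) {
    arch <- parse_architecture(raw)
    expect_identical(detect_tandem_cbms(arch),
                     brute_tandem(arch$classes),
                     info = raw)
  }
})

test_that("CBM-structure counting is presence-based per protein", {
  tab <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    genome_id = "G1",
    architecture = c("CBM11+CBM11+CBM11+GH51", "GH13", "CBM26"),
    stringsAsFactors = FALSE)
  prof <- count_cbm_structures(tab)
  expect_equal(prof$n_cbm_structures, 1L)
  expect_equal(prof$max_tandem_run, 3L)
  expect_equal(prof$cbm_families, "CBM11")
  expect_equal(prof$catalytic_families, "GH51")

  empty <- count_cbm_structures(tab[0, ])
  expect_equal(empty$n_cbm_structures, 0L)
  expect_equal(empty$n_proteins, 0L)

  # invariant to token order within a protein
  perm <- tab
  perm$architecture[1] <- "GH51+CBM11+CBM11+CBM11"
  expect_equal(count_cbm_structures(perm)$n_cbm_structures, 1L)

  tab$genome_id <- c("G1", "G1", "G2")
  expect_error(count_cbm_structures(tab), "single genome")
})

test_that("structure counts equal an independent enumerator on fuzz", {
  raws <- random_archs(1000, seed = 123)
  tab <- data.frame(protein_id = sprintf("p%04d", seq_along(raws)),
                    genome_id = "G1", architecture = raws,
                    stringsAsFactors = FALSE)
  prof <- count_cbm_structures(tab)
  # brute force: re-tokenize with a plain split and scan for both classes
  brute <- sum(vapply(raws, function(r) {
    toks <- strsplit(r, "[+|]")[[1]]
    any(grepl("^CBM[0-9]", toks)) &&
      any(grepl("^(GH|PL|CE|AA)[0-9]", toks))
  }, logical(1)))
  expect_equal(prof$n_cbm_structures, brute)
})

test_that("group ranking reports median fold differences and a rank test", {
  mk_prof <- function(gid, n) structure(
    list(genome_id = gid, n_proteins = 100L, n_cbm_structures = n,
         max_tandem_run = 2L), class = "genome_cbm_profile")
  profs <- c(lapply(1:5, function(i) mk_prof(paste0("A", i), 30)),
             lapply(1:5, function(i) mk_prof(paste0("B", i), 3)))
  grp <- setNames(rep(c("rich", "poor"), each = 5),
                  c(paste0("A", 1:5), paste0("B", 1:5)))
  rank <- genome_cbm_ranking(profs, grp)
  expect_equal(rank$fold_difference$fold_difference, 10)
  expect_lt(rank$p_value, 0.05)

  # equal count profiles in both groups: fold difference of medians is 1
  profs_eq <- c(lapply(1:5, function(i) mk_prof(paste0("A", i), 30)),
                lapply(1:5, function(i) mk_prof(paste0("B", i), 30)))
  same <- genome_cbm_ranking(profs_eq, grp)
  expect_equal(same$fold_difference$fold_difference, 1)
})

test_that("simulated CBM-rich genomes rank above poor ones", {
  wins <- vapply(1:5, function(s) {
    tab <- simulate_domain_annotations(12, 120, cbm_rich_fraction = 0.5,
                                       seed = 400 + s)
    profs <- profile_genomes(tab)
    rich <- attr(tab, "rich_genomes")
    grp <- setNames(ifelse(names(profs) %in% rich, "rich", "poor"),
                    names(profs))
    rk <- genome_cbm_ranking(profs, grp)
    med <- setNames(rk$summary$median, rk$summary$group)
    med["rich"] > med["poor"]
  }, logical(1))
  expect_true(all(wins))
})
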