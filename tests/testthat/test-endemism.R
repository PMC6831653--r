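test_that("richness and endemism summarize presence and annotations", {
  cl <- tiny_checklist()
  out <- richness_endemism(cl)
  expect_equal(out$n_species, c(5L, 3L, 2L))
  expect_equal(out$n_endemic, c(1L, 0L, 0L))     # sp1 endemic to A
  expect_equal(out$pct_endemic[1], 20.0)
  ws <- attr(out, "widespread")
  expect_equal(ws$n_widespread, 1L)              # only sp3 spans A, B and C

  out2 <- richness_endemism(cl, c("A", "B"))
  expect_equal(attr(out2, "widespread")$n_widespread, 3L)  # sp2, sp3, sp5

  expect_error(richness_endemism(cl, c("A", "Q")),
               class = "archipel_config_error")
  bad <- cl; bad$endemic_scope[2] <- "Q"
  expect_error(richness_endemism(bad), class = "archipel_validation_error")
})

test_that("published endemism percentages reproduce from printed counts", {
  counts <- readr::read_tsv(extdata("archipelago_richness.tsv"),
                            show_col_types = FALSE)
  out <- endemism_from_counts(counts)
  gast <- out[out$group == "gastropods", ]
  expect_equal(gast$pct_endemic[gast$region == "CAB"], 44.1)  # 268/608
  expect_equal(gast$pct_endemic[gast$region == "AZO"], 13.2)  # 37/280
  expect_equal(gast$pct_endemic[gast$region == "CAN"], 11.8)  # 96/811
  fish <- out[out$group == "fishes", ]
  expect_equal(fish$pct_endemic[fish$region == "CAB"], 7.3)   # 22/303

  # empty region: percentage undefined, not zero
  empty <- endemism_from_counts(tibble::tibble(region = "X", n_species = 0L,
                                               n_endemic = 0L))
  expect_true(is.na(empty$pct_endemic))
})

test_that("provincial index reproduces the published PIT/PCT arithmetic", {
  counts <- readr::read_tsv(extdata("provincial_index_counts.tsv"),
                            show_col_types = FALSE)
  cab <- provincial_index_from_counts(counts[counts$region == "CAB", -1],
                                      region = "CAB")
  expect_equal(round_half_up(cab$pct, 1), 29.5)
  expect_equal(cab$status, "subprovince")
  # per-family values
  fam <- cab$families
  expect_equal(fam$pit[fam$family == "Conidae"], 100 * 52 / 55)
  expect_equal(round_half_up(fam$pit[fam$family == "Conidae"], 1), 94.5)
  expect_true(is.na(fam$pit[fam$family == "Turbinellidae"]))  # N = 0 -> n.a.

  waf <- provincial_index_from_counts(counts[counts$region == "WAF", -1],
                                      region = "WAF")
  expect_equal(round_half_up(waf$pct, 1), 6.6)
  expect_equal(waf$status, "none")

  # occupied families with zero endemics give PCT 0.0, not n.a.
  mad <- provincial_index_from_counts(counts[counts$region == "MAD", -1])
  expect_equal(mad$pct, 0)
  expect_equal(mad$status, "none")

  # no species in any index family: PCT undefined
  azo <- provincial_index_from_counts(
    tibble::tibble(family = character(), n_species = integer(),
                   n_endemic = integer()))
  expect_true(is.na(azo$pct))
  expect_equal(azo$status, "not_applicable")
})

test_that("provincial index computes from a checklist through family and genus maps", {
  cl <- as_checklist(tibble::tibble(
    species = c("Conus a", "Conus b", "Modulus m", "Hexaplex h", "Oliva o",
                "Rissoa r"),
    taxon_group = "gastropods",
    family = c("Conidae", "Conidae", "Modulidae", "Muricidae", "Olividae",
               "Rissoidae"),
    genus = c("Conus", "Conus", "Modulus", "Hexaplex", "Oliva", "Rissoa"),
    endemic_scope = c("CAB", NA, NA, "CAB", "CAB", NA),
    CAB = c(1L, 1L, 1L, 1L, 1L, 1L),
    WAF = c(0L, 1L, 1L, 0L, 0L, 1L)
  ))
  # Modulidae by family; Hexaplex -> Muricinae and Oliva -> Olivinae by genus
  pi_cab <- provincial_index(cl, "CAB")
  fam <- pi_cab$families
  expect_equal(fam$n_species[fam$family == "Conidae"], 2L)
  expect_equal(fam$n_endemic[fam$family == "Conidae"], 1L)
  expect_equal(fam$n_species[fam$family == "Muricinae"], 1L)
  expect_equal(fam$n_endemic[fam$family == "Muricinae"], 1L)
  expect_equal(fam$n_species[fam$family == "Olivinae"], 1L)
  # PIT: Conidae 50, Muricinae 100, Olivinae 100, Modulidae 0 -> PCT 25
  expect_equal(pi_cab$pct, 25)
  expect_equal(pi_cab$status, "subprovince")
})

test_that("status classification uses the documented boundaries", {
  expect_equal(classify_provincial_status(29.5), "subprovince")
  expect_equal(classify_provincial_status(6.6), "none")
  expect_equal(classify_provincial_status(50.0), "subprovince")
  expect_equal(classify_provincial_status(50.0 + 1e-9), "province")
  expect_equal(classify_provincial_status(25.0), "subprovince")
  expect_equal(classify_provincial_status(25.0 - 1e-9), "none")
  expect_equal(classify_provincial_status(NA_real_), "not_applicable")
  expect_error(classify_provincial_status(120),
               class = "archipel_validation_error")
})

test_that("PCT invariants: order invariance and monotonicity", {
  counts <- tibble::tibble(
    family = c("Conidae", "Modulidae"),
    n_species = c(10L, 4L), n_endemic = c(5L, 2L))
  p1 <- provincial_index_from_counts(counts)
  p2 <- provincial_index_from_counts(counts[2:1, ])
  expect_equal(p1$pct, p2$pct)

  # single occupied family: PCT = PIT / 10
  single <- provincial_index_from_counts(
    tibble::tibble(family = "Conidae", n_species = 8L, n_endemic = 6L))
  expect_equal(single$pct, (100 * 6 / 8) / 10)

  # adding a non-endemic species weakly decreases PIT and PCT
  bigger <- counts; bigger$n_species[1] <- bigger$n_species[1] + 1L
  expect_lt(provincial_index_from_counts(bigger)$pct, p1$pct)
})

test_that("shared endemics summarize occupancy and combinations", {
  arch <- c("AZO", "MAD", "SEL", "CAN", "CAB")
  combos <- readr::read_tsv(extdata("gastropod_shared_combos_synthetic.tsv"),
                            show_col_types = FALSE)
  cl <- checklist_from_combos(combos, archipelagos = arch,
                              taxon_group = "gastropods")
  expect_equal(nrow(cl), 104)
  se <- shared_endemics(cl, arch)
  expect_equal(sum(se$occupancy$n), 104)
  expect_equal(se$occupancy$n[se$occupancy$occupancy == 2], 56L)
  expect_equal(se$occupancy$pct, c(53.8, 33.7, 9.6, 2.9)[order(2:5)])
  cmb <- se$combinations
  expect_equal(cmb$n[cmb$combo == "MAD+SEL+CAN"], 27L)
  expect_equal(cmb$n[cmb$combo == "MAD+CAN"], 17L)

  # combination counts aggregate to occupancy counts by subset size
  agg <- tapply(cmb$n, cmb$size, sum)
  expect_equal(as.vector(agg[as.character(2:5)]),
               se$occupancy$n[match(2:5, se$occupancy$occupancy)])

  # occupancy percentages sum to 100 (within rounding)
  expect_equal(sum(se$occupancy$pct), 100, tolerance = 0.2)

  # a "shared endemic" recorded in fewer than 2 archipelagos is an error
  bad <- cl
  bad[[arch[1]]][bad$endemic_scope == "AZO+MAD"] <- 0L
  bad <- suppressWarnings(as_checklist(tibble::as_tibble(bad)))
  expect_error(shared_endemics(bad, arch),
               class = "archipel_validation_error")
})

test_that("shared_endemics_matrix inverts the table and feeds clustering", {
  arch <- c("AZO", "MAD", "SEL", "CAN", "CAB")
  combos <- readr::read_tsv(extdata("gastropod_shared_combos_synthetic.tsv"),
                            show_col_types = FALSE)
  cl <- checklist_from_combos(combos, archipelagos = arch)
  se <- shared_endemics(cl, arch)
  back <- shared_endemics_matrix(se)
  expect_equal(regions(back), arch)
  # column sums equal per-archipelago shared-endemic counts
  m <- presence_matrix(back)
  for (r in arch) {
    expect_equal(unname(rowSums(m)[r]),
                 sum(vapply(strsplit(se$species$combo, "+", fixed = TRUE),
                            function(s) r %in% s, logical(1))))
  }
  # round trip reproduces the occupancy distribution
  se2 <- shared_endemics(back, arch)
  expect_equal(se2$occupancy, se$occupancy)

  # single species in two archipelagos
  one <- checklist_from_combos(tibble::tibble(combo = "A+B", n = 1L),
                               archipelagos = c("A", "B"))
  se1 <- shared_endemics(one, c("A", "B"))
  expect_equal(se1$occupancy$n[se1$occupancy$occupancy == 2], 1L)
  expect_equal(se1$occupancy$pct[se1$occupancy$occupancy == 2], 100)
})

test_that("occupancy_from_counts pools the per-taxon occupancy rows", {
  occ <- readr::read_tsv(extdata("shared_endemics_occupancy.tsv"),
                         show_col_types = FALSE)
  out <- occupancy_from_counts(occ)
  all_row <- out[out$group == "all", ]
  expect_equal(sum(all_row$n), 150L)
  expect_equal(all_row$n[all_row$occupancy == 5], 10L)
  expect_equal(all_row$pct[all_row$occupancy == 5], 6.7)
  expect_equal(all_row$pct[all_row$occupancy == 4], 11.3)
  expect_equal(all_row$pct[all_row$occupancy == 3], 31.3)
  expect_equal(all_row$pct[all_row$occupancy == 2], 50.7)
  gast <- out[out$group == "gastropods", ]
  expect_equal(gast$pct[gast$occupancy == 2], 53.8)
})
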