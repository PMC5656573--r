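mk_mirna <- function(seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
}

test_that("find_seed_sites reports constructed sites with correct types and offsets", {
  m <- mk_mirna(1)
  rc7 <- lincnet::revcomp(substr(m, 2, 8))
  tgt <- paste0(strrep("C", 10), rc7, "A", strrep("C", 20))
  got <- find_seed_sites(tgt, m, "m1")
  expect_true(any(got$start == 10 & got$site_type == "8mer"))
  # the seed-6 core inside the 8mer is reported at its own offset
  expect_true(any(got$start == 11 & got$site_type == "7mer-A1"))

  tgt2 <- paste0(strrep("C", 10), rc7, "G", strrep("C", 20))
  got2 <- find_seed_sites(tgt2, m, "m1")
  expect_true(any(got2$start == 10 & got2$site_type == "7mer-m8"))

  expect_equal(nrow(find_seed_sites(strrep("C", 50), m, "m1")), 0L)
  expect_error(find_seed_sites("ACGTACG", m), "shorter")
})

test_that("find_seed_sites agrees with the naive substring oracle", {
  set.seed(6)
  for (i in 1:30) {
    m <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    # AT-rich targets make chance seed matches likely
    tgt <- paste(sample(c("A", "C", "G", "T"), 500, TRUE, prob = c(.35, .15, .15, .35)),
      collapse = ""
    )
    got <- find_seed_sites(tgt, m, "m")
    want <- oracle_sites(tgt, m)
    expect_equal(got$start, want$start)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("unique sites pool over molecules and deduplicate", {
  sl <- tibble::tibble(mirna_id = rep(c("m1", "m2"), c(2, 2)), start = c(1, 10, 3, 30))
  sm <- tibble::tibble(mirna_id = rep(c("m1", "m2"), c(3, 2)), start = c(5, 15, 25, 7, 70))
  expect_equal(count_unique_sites(sl, sm, c("m1", "m2")), 9L)
  expect_equal(count_unique_sites(sl, sm, "m1"), 5L)
  # a duplicated record counts once
  sl2 <- dplyr::bind_rows(sl, sl[1, ])
  expect_equal(count_unique_sites(sl2, sm, c("m1", "m2")), 9L)
})

cerna_fixture <- function(seed = 99, n_trip = 4, n_neg = 6) {
  set.seed(seed)
  mirnas <- simulate_mirnas(2 * n_trip, seed = seed)
  lnc <- tibble::tibble(
    id = paste0("L", seq_len(n_trip + n_neg)),
    sequence = vapply(seq_len(n_trip + n_neg), function(i) {
      paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    }, character(1))
  )
  utr <- tibble::tibble(
    id = paste0("M", seq_len(n_trip + n_neg)),
    sequence = vapply(seq_len(n_trip + n_neg), function(i) {
      paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    }, character(1))
  )
  triplets <- tibble::tibble(
    lncrna_id = paste0("L", seq_len(n_trip)),
    mrna_id = paste0("M", seq_len(n_trip)),
    mirna_ids = lapply(seq_len(n_trip), function(t) mirnas$id[c(2 * t - 1, 2 * t)])
  )
  cfg <- sim_config(seed = seed)
  pl <- plant_mre_sites(lnc, utr, mirnas, triplets, cfg)
  # profiles: planted pairs share a latent pattern, negatives are noise
  n_s <- 9
  prof <- matrix(rnorm((nrow(lnc) + nrow(utr)) * n_s), ncol = n_s,
    dimnames = list(c(lnc$id, utr$id), paste0("s", 1:n_s))
  )
  for (t in seq_len(n_trip)) {
    z <- rnorm(n_s, sd = 3)
    prof[paste0("L", t), ] <- z + rnorm(n_s, sd = 0.3)
    prof[paste0("M", t), ] <- z + rnorm(n_s, sd = 0.3)
  }
  list(pl = pl, mirnas = mirnas, prof = prof, triplets = triplets,
       lnc_ids = lnc$id)
}

test_that("build_cerna_network admits exactly the pairs passing all three gates", {
  fx <- cerna_fixture()
  net <- build_cerna_network(
    fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas, fx$prof, fx$lnc_ids
  )
  want <- paste(fx$triplets$lncrna_id, fx$triplets$mrna_id)
  got <- paste(net$edges$lncrna_id, net$edges$mrna_id)
  expect_setequal(got, want)
  expect_true(all(net$edges$n_shared_mirnas >= 2))
  expect_true(all(net$edges$n_unique_sites >= 8))
  expect_true(all(net$edges$pearson_r > 0.7))
})

test_that("each threshold individually rejects a pair", {
  fx <- cerna_fixture(seed = 123)
  # correlation gate: r below cutoff even with perfect sites
  prof_flat <- fx$prof
  prof_flat[fx$triplets$lncrna_id[1], ] <- rnorm(9)
  net <- build_cerna_network(
    fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas, prof_flat, fx$lnc_ids
  )
  expect_false(fx$triplets$lncrna_id[1] %in% net$edges$lncrna_id)
  # shared-miRNA gate: restricting the miRNA catalog to one per triplet
  net2 <- build_cerna_network(
    fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas[seq(1, nrow(fx$mirnas), by = 2), ],
    fx$prof, fx$lnc_ids
  )
  expect_equal(nrow(net2$edges), 0L)
  # site gate: raising the requirement above the planted count
  net3 <- build_cerna_network(
    fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas, fx$prof, fx$lnc_ids,
    min_unique_sites = 50
  )
  expect_equal(nrow(net3$edges), 0L)
})

test_that("raising any threshold yields a subset network", {
  fx <- cerna_fixture(seed = 5)
  base <- build_cerna_network(
    fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas, fx$prof, fx$lnc_ids
  )
  for (args in list(
    list(min_shared_mirnas = 3L), list(min_unique_sites = 10L), list(min_r = 0.9)
  )) {
    net <- do.call(build_cerna_network, c(
      list(fx$pl$lnc_seqs, fx$pl$utr_seqs, fx$mirnas, fx$prof, fx$lnc_ids),
      args
    ))
    expect_true(all(
      paste(net$edges$lncrna_id, net$edges$mrna_id) %in%
        paste(base$edges$lncrna_id, base$edges$mrna_id)
    ))
  }
})

test_that("shuffling a sequence destroys its pairs even at perfect correlation", {
  fx <- cerna_fixture(seed = 8)
  lnc <- fx$pl$lnc_seqs
  i <- match(fx$triplets$lncrna_id[1], lnc$id)
  set.seed(1)
  lnc$sequence[i] <- paste(
    sample(strsplit(lnc$sequence[i], "")[[1]]), collapse = ""
  )
  prof <- fx$prof
  prof[fx$triplets$mrna_id[1], ] <- prof[fx$triplets$lncrna_id[1], ] # r = 1
  net <- build_cerna_network(lnc, fx$pl$utr_seqs, fx$mirnas, prof, fx$lnc_ids)
  expect_false(fx$triplets$lncrna_id[1] %in% net$edges$lncrna_id)
})

test_that("network summaries tally nodes and degrees consistently", {
  empty <- structure(
    list(edges = tibble::tibble(
      lncrna_id = character(), mrna_id = character(),
      shared_mirna_ids = list(), n_shared_mirnas = integer(),
      n_unique_sites = integer(), pearson_r = numeric()
    ), skipped = NULL, thresholds = list()),
    class = "cerna_network"
  )
  s <- network_summary(empty)
  expect_equal(c(s$n_edges, s$n_lncrnas, s$n_mrnas), c(0L, 0L, 0L))

  one <- empty
  one$edges <- tibble::tibble(
    lncrna_id = c("L1", "L1"), mrna_id = c("M1", "M2"),
    shared_mirna_ids = list(c("a", "b"), c("a", "b")),
    n_shared_mirnas = 2L, n_unique_sites = 9L, pearson_r = 0.9
  )
  s1 <- network_summary(one)
  expect_equal(c(s1$n_edges, s1$n_lncrnas, s1$n_mrnas), c(2L, 1L, 2L))
  expect_equal(sort(s1$degree$degree, decreasing = TRUE)[1], 2L)
  expect_equal(glance(one)$n_edges, 2L)
})
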