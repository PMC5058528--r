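test_that("fixtures are deterministic given the seed", {
  cfg <- sim_config(seed = 5, n_locations = 2, n_per_group_per_location = 8,
                    n_neutral_loci = 30, n_outlier_loci = 3,
                    n_seq_per_host = 10)
  a <- simulate_dominant_markers(cfg)
  b <- simulate_dominant_markers(cfg)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$truth$p_host, b$truth$p_host)
  sa <- simulate_sequences(cfg)
  sb <- simulate_sequences(cfg)
  expect_identical(sa$alignment$seqs, sb$alignment$seqs)
  expect_identical(sa$truth$phases, sb$truth$phases)
})

test_that("zero-divergence limit gives near-zero estimated FST", {
  cfg <- sim_config(seed = 21, background_fst = 1e-12, n_outlier_loci = 0,
                    miscall_rate = 0)
  mk <- simulate_dominant_markers(cfg)
  expect_true(all(mk$truth$p_host[1, ] == mk$truth$p_host[2, ]))
  f <- fst_dominant(mk$matrix, "host", n_perm = 0)
  expect_lt(abs(f$fst), 0.02)
})

test_that("planted outliers sit far above the neutral FST background", {
  cfg <- sim_config(seed = 22, miscall_rate = 0)
  mk <- simulate_dominant_markers(cfg)
  f <- fst_dominant(mk$matrix, "host", n_perm = 0)
  is_out <- f$per_locus$locus %in% mk$truth$outlier_loci
  expect_gt(mean(f$per_locus$fst[is_out], na.rm = TRUE),
            mean(f$per_locus$fst[!is_out], na.rm = TRUE) + 0.2)
  # every truth-known fixture keeps the ordering
  expect_gt(min(colMeans(matrix(f$per_locus$fst[is_out], nrow = 1))),
            trimmed_mean_fst(f$per_locus$fst[!is_out]))
})

test_that("replicate mismatch fraction follows 2m(1-m)", {
  m <- 0.05
  cfg <- sim_config(seed = 23, miscall_rate = m, n_replicate_pairs = 60,
                    n_neutral_loci = 250, n_outlier_loci = 0)
  mk <- simulate_dominant_markers(cfg)
  est <- estimate_error_rate(mk$matrix)
  expected <- 2 * m * (1 - m)
  n_calls <- 60 * 250
  tol <- 3 * sqrt(expected * (1 - expected) / n_calls)
  expect_lt(abs(est - expected), tol)
  # no miscalls -> replicates identical
  cfg0 <- sim_config(seed = 23, miscall_rate = 0,
                     n_neutral_loci = 40, n_outlier_loci = 0)
  expect_identical(estimate_error_rate(simulate_dominant_markers(cfg0)$matrix),
                   0)
})

test_that("true phases explain every IUPAC consensus exactly", {
  cfg <- sim_config(seed = 24, n_seq_per_host = 25)
  sq <- simulate_sequences(cfg)
  for (id in names(sq$truth$phases)) {
    ph <- sq$truth$phases[[id]]
    a <- strsplit(ph[1], "")[[1]]
    b <- strsplit(ph[2], "")[[1]]
    expect_identical(paste(hostscan:::iupac_code(a, b), collapse = ""),
                     unname(sq$alignment$seqs[id]))
  }
})

test_that("host-diagnostic SNP respects configured frequencies", {
  # fixed difference
  cfg <- sim_config(seed = 25, host_snp_freqs = c(1, 0), n_seq_per_host = 20)
  sq <- simulate_sequences(cfg)
  site <- sq$truth$diagnostic_site
  alleles <- vapply(names(sq$truth$phases), function(id) {
    ph <- sq$truth$phases[[id]]
    paste(substr(ph[1], site, site), substr(ph[2], site, site))
  }, "")
  host <- sq$alignment$meta$host
  derived <- sq$truth$alleles$derived[match(site, sq$truth$snp_sites)]
  h1 <- alleles[host == cfg$hosts[1]]
  h2 <- alleles[host == cfg$hosts[2]]
  expect_true(all(grepl(derived, h1)))
  expect_false(any(grepl(derived, h2)))
  # single haplotype per pool, no diagnostic variation -> no diversity
  cfg2 <- sim_config(seed = 26, hap_pool_sizes = c(1, 1),
                     host_snp_freqs = c(0, 0), n_seq_per_host = 6)
  sq2 <- simulate_sequences(cfg2)
  haps <- em_phase(sq2$alignment)
  s <- haplotype_summary(haps, "host")
  by_host <- s[s$group != "total", ]
  expect_true(all(by_host$Hd == 0))
  expect_true(all(by_host$pi == 0))
})

test_that("host haplotype-pool asymmetry is recovered downstream", {
  cfg <- sim_config(seed = 27, n_seq_per_host = 135)
  sq <- simulate_sequences(cfg)
  haps <- em_phase(sq$alignment)
  s <- haplotype_summary(haps, "host")
  H1 <- s$H[s$group == cfg$hosts[1]]
  H2 <- s$H[s$group == cfg$hosts[2]]
  expect_gt(H1, 1.5 * H2)         # ancestral pool roughly twice as rich
  expect_lte(H1, 2 * cfg$hap_pool_sizes[1])
  expect_gt(H1, 0.6 * cfg$hap_pool_sizes[1])
})

test_that("fixture sets round-trip losslessly through the readers", {
  cfg <- sim_config(seed = 28, n_locations = 2, n_per_group_per_location = 6,
                    n_neutral_loci = 25, n_outlier_loci = 5,
                    n_seq_per_host = 8)
  mk <- simulate_dominant_markers(cfg)
  sq <- simulate_sequences(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_set(mk$matrix, sq$alignment,
                             list(markers = mk$truth, sequences = NULL),
                             dir)
  m2 <- read_marker_tsv(paths[["markers"]])
  expect_identical(m2$calls, mk$matrix$calls)
  expect_identical(m2$meta$host, mk$matrix$meta$host)
  expect_identical(m2$loci$primer, mk$matrix$loci$primer)
  a2 <- read_diploid_fasta(paths[["sequences"]])
  expect_identical(unname(a2$seqs), unname(sq$alignment$seqs))
  expect_identical(a2$meta$host, sq$alignment$meta$host)
  expect_identical(a2$meta$location, sq$alignment$meta$location)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(sort(truth$markers$outlier_loci),
                   sort(mk$truth$outlier_loci))
  expect_length(truth$markers$outlier_loci, cfg$n_outlier_loci)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(host_snp_freqs = c(2, 0)), "host_snp_freqs")
  expect_error(sim_config(n_seq_snps = 500), "third codon")
  expect_error(simulate_dominant_markers(
    sim_config(n_per_group_per_location = 1)), "FST undefined")
})
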