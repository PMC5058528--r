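test_that("SNP calling expands IUPAC codes and flags oddities", {
  # invariant alignment -> no SNPs
  inv <- toy_alignment(list(c("ACGTAC", "ACGTAC"), c("ACGTAC", "ACGTAC")))
  expect_identical(nrow(call_snps(inv)), 0L)
  # A/A, A/T (=W), T/T at one column -> alleles A and T, 3 copies each
  aln <- toy_alignment(list(c("AACGGT", "AACGGT"),
                            c("AACGGT", "TACGGT"),
                            c("TACGGT", "TACGGT")))
  tab <- call_snps(aln)
  expect_identical(tab$position, 1L)
  expect_setequal(c(tab$a1, tab$a2), c("A", "T"))
  expect_identical(c(tab$n1, tab$n2), c(3L, 3L))
  # columns containing N are excluded
  alnN <- toy_alignment(list(c("AACGGT", "AACGGT"),
                             c("NACGGT", "NACGGT")))
  expect_identical(nrow(call_snps(alnN)), 0L)
  # >2 alleles flagged as non-biallelic
  aln3 <- toy_alignment(list(c("AAA", "AAA"), c("CAA", "CAA"),
                             c("GAA", "GAA")))
  t3 <- call_snps(aln3)
  expect_false(t3$biallelic[1])
})

test_that("SNP positions on simulated data match the recorded truth", {
  cfg <- sim_config(seed = 51, n_seq_per_host = 40)
  sq <- simulate_sequences(cfg)
  tab <- call_snps(sq$alignment)
  expect_true(all(tab$position %in% sq$truth$snp_sites))
  expect_true(all(tab$codon_pos == 3L))
})

test_that("phasing is exact and fully confident at <= 1 het site", {
  aln <- toy_alignment(list(c("AAT", "AAT"), c("AAT", "ACT"),
                            c("ACT", "ACT"), c("AAT", "AAT")))
  haps <- em_phase(aln)
  expect_true(all(haps$pairs$confidence == 1))
  expect_true(all(haps$pairs$phased))
})

test_that("homozygote anchoring resolves a double heterozygote", {
  # many AB/AB and ab/ab homozygotes anchor the coupling phase
  pairs <- c(replicate(6, c("ATAAGG", "ATAAGG"), simplify = FALSE),
             replicate(6, c("GTAAGC", "GTAAGC"), simplify = FALSE),
             list(c("ATAAGG", "GTAAGC")))
  haps <- em_phase(toy_alignment(pairs))
  dh <- haps$pairs[13, ]
  got <- sort(c(haps$haplotypes[[dh$hap1]], haps$haplotypes[[dh$hap2]]))
  expect_identical(got, sort(c("AG", "GC")))
  # exact posterior by enumeration: pairs {AG,GC} vs {AC,GG};
  # EM converges to f(AG) = f(GC) = 13/26 * .., repulsion haps ~ 0, so the
  # coupling pair has posterior ~ 1
  expect_gt(dh$confidence, 0.95)
})

test_that("phasing recovers true phases on skewed truth-known pools", {
  cfg <- sim_config(seed = 52, n_seq_per_host = 60)
  sq <- simulate_sequences(cfg)
  haps <- em_phase(sq$alignment)
  snp <- haps$snp_pos
  tr <- sq$truth$phases
  hits <- 0; tot <- 0
  for (i in seq_len(nrow(haps$pairs))) {
    if (!haps$pairs$phased[i]) next
    id <- haps$pairs$sample_id[i]
    t1 <- paste(strsplit(tr[[id]][1], "")[[1]][snp], collapse = "")
    t2 <- paste(strsplit(tr[[id]][2], "")[[1]][snp], collapse = "")
    e1 <- haps$haplotypes[[haps$pairs$hap1[i]]]
    e2 <- haps$haplotypes[[haps$pairs$hap2[i]]]
    tot <- tot + 1
    hits <- hits + ((t1 == e1 && t2 == e2) || (t1 == e2 && t2 == e1))
  }
  expect_gt(tot, 0.7 * nrow(haps$pairs))
  expect_gte(hits / tot, 0.9)
})

test_that("haplotype summaries match brute-force oracles", {
  # two haplotypes at 50/50 differing at 1 site, 4 copies
  pairs <- list(c("AATT", "AATT"), c("AGTT", "AGTT"))
  haps <- em_phase(toy_alignment(pairs, host = c("glabra", "glabra")))
  s <- haplotype_summary(haps, grouping = NULL)
  expect_equal(s$Hd, (4 / 3) * (1 - 0.5), tolerance = 1e-12)
  expect_equal(s$pi, (1 / 4) * (4 / 6), tolerance = 1e-12)
  expect_identical(s$Sn, 0L)
  # identical copies -> all zeros
  same <- em_phase(toy_alignment(list(c("AATT", "AATT"),
                                      c("AATT", "AATT"))))
  s0 <- haplotype_summary(same, grouping = NULL)
  expect_true(all(c(s0$Hd, s0$pi, s0$Rm) == 0))
  # random richer group vs the exhaustive pairwise oracle
  cfg <- sim_config(seed = 53, n_seq_per_host = 5)
  sq <- simulate_sequences(cfg)
  hs <- em_phase(sq$alignment)
  s2 <- haplotype_summary(hs, grouping = NULL)
  copies <- hostscan:::hap_copies(hs)
  strings <- hs$haplotypes[copies]
  expect_equal(s2$Hd, oracle_hd(strings), tolerance = 1e-12)
  expect_equal(s2$pi,
               oracle_pi(unname(strings), hs$aln_length) *
                 hs$aln_length / hs$aln_length,
               tolerance = 1e-12)
})

test_that("Rm implements the four-gamete interval bound", {
  # one interval with all four gametes
  h <- c("AA", "AT", "TA", "TT")
  expect_identical(hostscan:::rm_four_gamete(h), 1L)
  expect_identical(hostscan:::rm_four_gamete(c("AA", "AT", "TA")), 0L)
  # order invariance and the p-1 cap on random instances
  set.seed(54)
  for (r in 1:5) {
    K <- 6
    hs <- unique(replicate(8, paste(sample(c("A", "G"), K, TRUE),
                                    collapse = "")))
    rm1 <- hostscan:::rm_four_gamete(hs)
    rm2 <- hostscan:::rm_four_gamete(rev(hs))
    expect_identical(rm1, rm2)
    expect_lte(rm1, K - 1)
  }
})

test_that("F84 distances match the closed-form oracle", {
  s1 <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  expect_identical(f84_distance(s1, s1), 0)
  set.seed(55)
  for (r in 1:5) {
    base <- sample(c("A", "C", "G", "T"), 400, TRUE)
    mut <- base
    idx <- sample(400, 12)
    mut[idx] <- vapply(mut[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    a <- paste(base, collapse = ""); b <- paste(mut, collapse = "")
    expect_equal(f84_distance(a, b), oracle_f84(a, b), tolerance = 1e-8)
    expect_equal(f84_distance(a, b), f84_distance(b, a))
  }
})

test_that("PhiST matches the brute-force AMOVA oracle", {
  # fixed haplotype difference between groups -> PhiST = 1
  pairs <- c(replicate(5, c("AAAA", "AAAA"), simplify = FALSE),
             replicate(5, c("AATA", "AATA"), simplify = FALSE))
  aln <- toy_alignment(pairs, host = rep(c("glabra", "coriacea"), each = 5))
  haps <- em_phase(aln)
  ph <- phi_st(haps, "host", n_perm = 99, seed = 1, distance = "hamming")
  expect_equal(ph$phi_st, 1, tolerance = 1e-12)
  expect_lt(ph$p, 0.1)
  # 6-copy toy vs the explicit variance-component oracle
  cfg <- sim_config(seed = 56, n_seq_per_host = 6)
  sq <- simulate_sequences(cfg)
  hs <- em_phase(sq$alignment)
  ph2 <- phi_st(hs, "host", n_perm = 0, distance = "hamming")
  p <- hs$pairs[hs$pairs$phased, ]
  grp <- hs$meta$host[match(p$sample_id, hs$meta$sample_id)]
  copies <- c(p$hap1, p$hap2)
  dm <- hostscan:::hamming_matrix(hs$haplotypes)
  rownames(dm) <- colnames(dm) <- names(hs$haplotypes)
  expect_equal(ph2$phi_st,
               oracle_phi(dm[copies, copies], rep(grp, 2)),
               tolerance = 1e-10)
  # degenerate all-identical input
  same <- em_phase(toy_alignment(c(replicate(2, c("AA", "AA"),
                                             simplify = FALSE),
                                   replicate(2, c("AA", "AA"),
                                             simplify = FALSE))))
  d0 <- phi_st(same, "host", n_perm = 0, distance = "hamming")
  expect_identical(d0$phi_st, 0)
  expect_true(d0$degenerate)
})

test_that("codon effects are classified by the standard genetic code", {
  # third-position AAT -> AAA: Asn -> Lys, nonsynonymous
  a1 <- toy_alignment(list(c("AATGGG", "AATGGG"), c("AAAGGG", "AAAGGG")))
  e1 <- annotate_codon_effect(a1)
  expect_identical(e1$effect, "nonsynonymous")
  expect_setequal(c(e1$aa1, e1$aa2), c("N", "K"))
  # third-position CTT -> CTC: Leu -> Leu, synonymous
  a2 <- toy_alignment(list(c("CTTGGG", "CTTGGG"), c("CTCGGG", "CTCGGG")))
  expect_identical(annotate_codon_effect(a2)$effect, "synonymous")
  # first-position GAT -> AAT: Asp -> Asn, nonsynonymous
  a3 <- toy_alignment(list(c("GATGGG", "GATGGG"), c("AATGGG", "AATGGG")))
  e3 <- annotate_codon_effect(a3)
  expect_identical(e3$effect, "nonsynonymous")
  expect_setequal(c(e3$aa1, e3$aa2), c("D", "N"))
  # all simulated SNPs sit in third positions; most are synonymous
  cfg <- sim_config(seed = 57, n_seq_per_host = 20)
  sq <- simulate_sequences(cfg)
  eff <- annotate_codon_effect(sq$alignment)
  expect_true(all(eff$codon_pos == 3))
  expect_true(all(eff$effect %in% c("synonymous", "nonsynonymous")))
})

test_that("phased FASTA export writes two records per individual", {
  cfg <- sim_config(seed = 58, n_seq_per_host = 6)
  sq <- simulate_sequences(cfg)
  hs <- em_phase(sq$alignment)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_phased_fasta(hs, path)
  x <- Biostrings::readBStringSet(path)
  expect_identical(length(x), 2L * sum(hs$pairs$phased))
  expect_true(all(grepl("_[ab]$", names(x))))
})
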