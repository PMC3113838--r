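# Seed-site scanning, Poisson significance, exact matching, annotation.

test_that("genome construction validates the alphabet", {
  expect_error(genome_sequence(""), "empty")
  expect_error(genome_sequence("ACGTN"), "ambiguity")
  g <- genome_sequence("ACGUACGU", circular = FALSE)   # U converted to T
  expect_equal(g$seq, "ACGTACGT")
  expect_equal(g$length, 8)
})

test_that("seed sites equal a brute-force window scan on a random genome", {
  set.seed(11)
  gseq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                       prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  for (circ in c(TRUE, FALSE)) {
    g <- genome_sequence(gseq, circular = circ)
    for (k in c(4, 5, 6)) {
      hits <- seed_sites(mir, g, k = k)
      oracle <- brute_seed_scan(mir, gseq, circular = circ, k = k)
      expect_equal(hits[c("start", "end", "strand")], oracle,
                   ignore_attr = TRUE)
    }
  }
})

test_that("seed parameter validation and strand restriction work", {
  g <- genome_sequence(strrep("ACGT", 100), circular = TRUE)
  expect_error(seed_sites("UGAGGUA", g, k = 3), "k must be")
  expect_error(seed_sites("UGAGGUA", g, k = 7, seed_start = 3), "3' end")
  both <- seed_sites("UGAGGUAGUAGGUUGUAUAGUU", g, k = 4)
  plus <- seed_sites("UGAGGUAGUAGGUUGUAUAGUU", g, k = 4, strands = "+")
  expect_equal(plus, both[both$strand == "+", ], ignore_attr = TRUE)
})

test_that("a site planted across the origin of a circular genome is found", {
  planted <- data.frame(seed = "UGAGCUC", position = 497, strand = "+")
  sim <- gen_genome_with_sites(500, planted = planted, background = "A",
                               circular = TRUE, seed = 1)
  hits <- seed_sites("UGAGCUCAAAAAAAA", sim$genome, k = 7)
  expect_true(497 %in% hits$start[hits$strand == "+"])
  linear <- genome_sequence(sim$genome$seq, circular = FALSE)
  hits_lin <- seed_sites("UGAGCUCAAAAAAAA", linear, k = 7)
  expect_false(497 %in% hits_lin$start)
})

test_that("the Poisson tail statistic follows its closed form", {
  g128 <- genome_sequence(strrep("ACGT", 32), circular = TRUE)  # L = 128
  # uniform composition, k = 4, both strands: lambda = 2 * 128 / 4^4 = 1
  pv <- poisson_match_pvalue(1, g128, "UGAG", composition = "uniform")
  expect_equal(pv$lambda, 1)
  expect_equal(pv$p_value, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_match_pvalue(0, g128, "UGAG", composition = "uniform")$p_value, 1)

  # lambda on the 16.5-kb scale and a brute-force tail sum
  set.seed(3)
  g <- genome_sequence(paste(sample(c("A", "C", "G", "T"), 16569,
                                    replace = TRUE), collapse = ""),
                       circular = TRUE)
  pv3 <- poisson_match_pvalue(3, g, "UGAGGUA", composition = "uniform")
  lam <- 2 * 16569 * 4^-7
  expect_equal(pv3$lambda, lam, tolerance = 1e-12)
  tail_sum <- 1 - sum(exp(-lam) * lam^(0:2) / factorial(0:2))
  expect_equal(pv3$p_value, tail_sum, tolerance = 1e-12)

  # genome-composition mode uses the mononucleotide frequencies of the site
  skew <- genome_sequence(paste(c(rep("A", 700), rep("C", 100),
                                  rep("G", 100), rep("T", 100)),
                                collapse = ""), circular = TRUE)
  pvg <- poisson_match_pvalue(0, skew, "AAAA", composition = "genome")
  f <- c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)
  expect_equal(pvg$lambda, 1000 * (0.1^4 + 0.7^4), tolerance = 1e-9)
})

test_that("the Poisson p-value is strictly monotone in the observed count", {
  g <- genome_sequence(strrep("ACGT", 500), circular = TRUE)
  p <- vapply(0:8, function(n)
    poisson_match_pvalue(n, g, "UGAGGUA")$p_value, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("mean hit count over random genomes matches lambda in uniform mode", {
  k <- 5
  L <- 2000
  lam <- 2 * L * 4^-k
  set.seed(21)
  counts <- vapply(1:200, function(i) {
    g <- genome_sequence(paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""),
                         circular = TRUE)
    nrow(seed_sites("ACGGCAAUGGCAUGGAC", g, k = k))
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 200))
})

test_that("exact mature matching recovers planted full-length copies", {
  set.seed(31)
  gseq <- paste(sample(c("A", "C", "G", "T"), 16000, replace = TRUE),
                collapse = "")
  mir_fwd <- chartr("T", "U", substr(gseq, 100, 121))
  hits <- exact_mature_match(mir_fwd, genome_sequence(gseq, circular = TRUE))
  expect_true(any(hits$start == 100 & hits$end == 121 & hits$strand == "+"))

  # a minus-strand copy: plant the reverse complement on the forward strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir_fwd))))
  gseq2 <- paste0(substr(gseq, 1, 499), rc, substr(gseq, 522, 16000))
  hits2 <- exact_mature_match(mir_fwd, genome_sequence(gseq2, circular = TRUE))
  expect_true(any(hits2$start == 500 & hits2$end == 521 & hits2$strand == "-"))

  # a random 22-mer equals a plain string-search oracle (almost surely 0 hits)
  rnd <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
  hits3 <- exact_mature_match(rnd, genome_sequence(gseq, circular = FALSE))
  oracle <- gregexpr(chartr("U", "T", rnd), gseq, fixed = TRUE)[[1]]
  n_fwd <- if (oracle[1] == -1) 0 else length(oracle)
  expect_equal(sum(hits3$strand == "+"), n_fwd)
})

test_that("reverse-complementing the genome swaps strands and maps coordinates", {
  set.seed(41)
  gseq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                collapse = "")
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  g <- genome_sequence(gseq, circular = FALSE)
  rc <- genome_sequence(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gseq))), circular = FALSE)
  h <- seed_sites(mir, g, k = 5)
  h_rc <- seed_sites(mir, rc, k = 5)
  L <- g$length
  mapped <- data.frame(start = L - h$end + 1, end = L - h$start + 1,
                       strand = ifelse(h$strand == "+", "-", "+"))
  mapped <- mapped[order(mapped$start, mapped$strand), ]
  expect_equal(h_rc[c("start", "end", "strand")], mapped, ignore_attr = TRUE)
})

test_that("hits are labeled with every overlapping feature", {
  # D-loop spans the origin and is represented split, as annotations require
  ann <- data.frame(gene = c("TRNE", "ND6", "RNR1", "DLOOP", "DLOOP"),
                    type = c("gene", "gene", "gene", "region", "region"),
                    start = c(14674, 14149, 648, 16024, 1),
                    end = c(14742, 14673, 1601, 16569, 576),
                    strand = c("-", "-", "+", "+", "+"))
  hits <- data.frame(start = c(14680, 14670, 5000),
                     end = c(14686, 14676, 5006), strand = "+")
  out <- annotate_hits(hits, ann, genome_length = 16569)
  expect_equal(out$genes[1], "TRNE")
  expect_setequal(strsplit(out$genes[2], ",")[[1]], c("ND6", "TRNE"))
  expect_equal(out$genes[3], "intergenic")
  # an origin-spanning hit is wrapped before the overlap test
  hits5 <- data.frame(start = 16565, end = 16578, strand = "+")
  expect_equal(annotate_hits(hits5, ann, genome_length = 16569)$genes, "DLOOP")
  # without any annotation, hits fall back to an explicit label
  expect_equal(annotate_hits(hits5, NULL)$genes, "unannotated")
})

test_that("scan_panel reports one row per miRNA with truth-consistent genes", {
  planted <- data.frame(seed = c("UGAGGUC", "CCAGGCA"),
                        position = c(120, 700), strand = c("+", "-"))
  sim <- gen_genome_with_sites(1600, planted = planted, background = "A",
                               features = 4, seed = 51)
  mirnas <- c(m1 = "UGAGGUCAAAAAAAAAAAAAAA",
              m2 = "CCAGGCAAAAAAAAAAAAAAAA",
              none = "GCGCGCGCGCGCGCGCGCGCGC")
  panel <- scan_panel(mirnas, sim$genome, annotation = sim$annotation)
  expect_equal(nrow(panel$table), 3)
  expect_equal(panel$table$n_hits[panel$table$mirna_id == "none"], 0)
  expect_equal(panel$table$p_value[panel$table$mirna_id == "none"], 1)
  # planted hits fall in the features that tile the planted coordinates
  expected_gene <- sim$annotation$gene[sim$annotation$start <= 120 &
                                         sim$annotation$end >= 126]
  expect_true(grepl(expected_gene,
                    panel$table$genes[panel$table$mirna_id == "m1"]))
  expect_warning(scan_panel(mirnas[1], sim$genome), "annotation")
})
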