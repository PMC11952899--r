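test_that("FASTA parsing handles headers, wrapping and sanitization policies", {
  path <- write_temp_fasta(c(">sp|P1|X some description", "MKR",
                             ">Q2 another", "MKKL", "LLK"))
  recs <- read_fasta(path)
  expect_identical(recs, c(P1 = "MKR", Q2 = "MKKLLLK"))

  # map policy: U -> C, '*' stripped, with a warning
  path2 <- write_temp_fasta(c(">a", "MU*R"))
  expect_warning(recs2 <- read_fasta(path2, "map"), "sanitized")
  expect_identical(unname(recs2[["a"]]), "MCR")

  # drop-residue removes nonstandard letters without mapping
  expect_warning(recs3 <- read_fasta(path2, "drop-residue"), "sanitized")
  expect_identical(unname(recs3[["a"]]), "MR")

  # drop-protein discards the whole record
  path3 <- write_temp_fasta(c(">a", "MU*R", ">b", "MKR"))
  expect_warning(recs4 <- read_fasta(path3, "drop-protein"), "dropping")
  expect_identical(names(recs4), "b")

  # duplicate accessions are an error naming the accession
  path4 <- write_temp_fasta(c(">x", "MK", ">x", "ML"))
  expect_error(read_fasta(path4), "x")

  # record empty after sanitization is dropped with a warning
  path5 <- write_temp_fasta(c(">gone", "XXX", ">keep", "MKR"))
  w <- capture_warnings(recs5 <- read_fasta(path5))
  expect_true(any(grepl("empty after sanitization", w)))
  expect_identical(names(recs5), "keep")

  expect_error(read_fasta(write_temp_fasta(character(0))), "empty")

  # round trip through write_fasta
  out <- tempfile(fileext = ".fa")
  write_fasta(recs, out, width = 4L)
  expect_identical(read_fasta(out), recs)
})

test_that("GRAVY matches the Kyte-Doolittle mean, including hand values", {
  expect_equal(compute_gravy("KK"), -3.9)
  expect_equal(compute_gravy("AILV"), (1.8 + 4.5 + 3.8 + 4.2) / 4)
  for (a in O_AA) expect_equal(compute_gravy(a), unname(O_KD[a]))
  set.seed(42)
  for (i in 1:100) {
    s <- o_random_seq(sample(1:300, 1))
    expect_equal(compute_gravy(s), o_gravy(s))
  }
  expect_error(compute_gravy(""), "empty")
})

test_that("amino-acid composition matches a naive count and sums to 1", {
  set.seed(43)
  for (i in 1:50) {
    s <- o_random_seq(sample(1:200, 1))
    comp <- aa_composition(s)
    expect_equal(unname(comp), unname(o_aacomp(s)))
    expect_equal(sum(comp), 1, tolerance = 1e-12)
  }
})

test_that("isoelectric point zeroes the charge model and behaves monotonically", {
  # glycine: only termini titrate; pI must sit between their pKa values
  pi_g <- compute_pi("G")
  expect_gt(pi_g, 5.5); expect_lt(pi_g, 6.5)
  expect_lt(compute_pi("EEEEEEEE"), 4.5)

  # dense grid-search oracle for the zero crossing of the net charge
  set.seed(44)
  for (i in 1:20) {
    s <- o_random_seq(sample(5:100, 1))
    grid <- seq(0, 14, by = 1e-4)
    q <- vapply(grid, function(ph) compute_net_charge(s, ph), numeric(1))
    cross <- which(diff(sign(q)) < 0)[1]
    expect_equal(compute_pi(s), grid[cross], tolerance = 2e-4)
    expect_lt(abs(compute_net_charge(s, compute_pi(s))), 1e-5)
  }

  # appending basic residues never lowers pI; acidic never raises it
  set.seed(45)
  for (i in 1:10) {
    s <- o_random_seq(30)
    expect_gte(compute_pi(paste0(s, "K")), compute_pi(s) - 1e-9)
    expect_lte(compute_pi(paste0(s, "E")), compute_pi(s) + 1e-9)
  }
})

test_that("LCR fraction equals the brute-force window-entropy scan", {
  expect_equal(compute_lcr_fraction(strrep("A", 50)), 1.0)
  expect_equal(compute_lcr_fraction("ACDEFGHIKLMNPQRSTVWY", 12, 2.2), 0.0)
  for (a in c("G", "S", "Q")) # homopolymers at least one window long
    expect_equal(compute_lcr_fraction(strrep(a, 12)), 1.0)
  set.seed(46)
  for (i in 1:50) {
    # mix plain random and biased (low-alphabet) sequences near the threshold
    L <- sample(5:200, 1)
    s <- if (i %% 2 == 0) o_random_seq(L)
         else paste(sample(c("G", "S", "R", "A"), L, TRUE), collapse = "")
    expect_equal(compute_lcr_fraction(s), o_lcr(s), info = s)
  }
  expect_error(compute_lcr_fraction("MKR", window = 1), "window")
})

test_that("physicochemical vector has the documented 19 entries and behaviour", {
  v <- compute_physchem("MKR")
  expect_identical(names(v), physchem_feature_names())
  expect_length(v, 19L)
  expect_equal(unname(v["length"]), 3)
  # molecular weight grows under extension
  set.seed(47)
  for (i in 1:10) {
    s <- o_random_seq(sample(10:50, 1))
    expect_gt(compute_physchem(paste0(s, "A"))[["mol_weight"]],
              compute_physchem(s)[["mol_weight"]])
  }
  expect_gt(v[["mol_weight"]], 0)
  expect_true(v[["lcr_fraction"]] >= 0 && v[["lcr_fraction"]] <= 1)
})

test_that("k-mer vocabulary selection ranks by abundance with alphabetical ties", {
  v <- select_kmer_vocabulary(c(a = "RGRG", b = "GGGG"), k = 2, top_n = 2)
  expect_identical(as.character(v[1:2]), c("GG", "RG"))  # GG=3, RG=2, GR=1

  # ties broken alphabetically: AB and BA both occur once
  v2 <- select_kmer_vocabulary(c(x = "KRKY"), k = 2, top_n = 3)
  expect_identical(as.character(v2), c("KR", "KY", "RK"))

  # requesting more k-mers than observed returns all, flagged
  expect_warning(v3 <- select_kmer_vocabulary(c(x = "AAA"), k = 2, top_n = 50),
                 "distinct")
  expect_identical(as.character(v3), "AA")
  expect_true(attr(v3, "short"))

  expect_error(select_kmer_vocabulary(c(x = "A"), k = 2), "length >= 2")
  expect_error(select_kmer_vocabulary(character(0), k = 2), "no positive")
})

test_that("k-mer fractions use overlapping counts over L - k + 1 windows", {
  expect_equal(unname(kmer_fractions("RGGRGG", c("RG", "GG", "GR"))),
               c(2 / 5, 2 / 5, 1 / 5))
  expect_equal(unname(kmer_fractions("RG", c("RGG", "GGR"))), c(0, 0))
  set.seed(48)
  for (i in 1:100) {
    s <- o_random_seq(sample(1:500, 1))
    for (k in 2:3) {
      vocab <- unique(c(vapply(1:5, function(j)
        paste(sample(O_AA, k, TRUE), collapse = ""), character(1)),
        if (k == 2) "RG" else "RGG"))
      fr <- kmer_fractions(s, vocab)
      expect_true(all(fr >= 0 & fr <= 1))
      denom <- max(nchar(s) - k + 1, 1)
      for (km in vocab) {
        expected <- if (nchar(s) < k) 0 else o_kmer_count(s, km) / denom
        expect_equal(unname(fr[km]), expected, info = paste(s, km))
      }
    }
  }
})

test_that("feature table has canonical shape, row equivariance and determinism", {
  b <- small_model_bundle()
  recs <- b$records[1:3]
  tab <- build_feature_table(recs, b$vocab)
  expect_identical(dim(tab), c(3L, 139L))
  expect_identical(rownames(tab), names(recs))
  aa_cols <- paste0("aa_", O_AA)
  expect_true(all(abs(rowSums(tab[, aa_cols]) - 1) < 1e-9))
  expect_true(all(is.finite(tab)))

  # permuting input records permutes rows identically
  perm <- c(3L, 1L, 2L)
  tab_perm <- build_feature_table(recs[perm], b$vocab)
  expect_identical(tab_perm, tab[perm, ])

  # bit-identical recomputation
  expect_identical(build_feature_table(recs, b$vocab), tab)

  expect_error(build_feature_table(recs[c(1, 1)], b$vocab), "uniquely named")
})
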