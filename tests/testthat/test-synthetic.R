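# synthetic-data module: hairpin templates, family evolution, genome
# planting, target sets

test_that("make_hairpin builds the designed topology deterministically", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 1)
  expect_equal(nchar(h$sequence), 66)
  expect_no_error(pairing_map(h$structure))   # balanced structure
  expect_equal(h$mature_span, c(40L, 62L))
  expect_equal(h$star_span, c(6L, 28L))
  # perfect stem: every mature position paired
  expect_equal(validate_hairpin(h)$n_paired, 22)
  # determinism
  expect_identical(make_hairpin(30, 6, 0, 0, "3p", seed = 1), h)
  expect_false(identical(make_hairpin(30, 6, 0, 0, "3p", seed = 2)$sequence,
                         h$sequence))
})

test_that("wobbles keep the dot-bracket pairing but change the duplex", {
  h <- make_hairpin(30, 6, 2, 0, "3p", seed = 1)
  h0 <- make_hairpin(30, 6, 0, 0, "3p", seed = 1)
  expect_identical(h$structure, h0$structure)
  # exactly 2 G.U pairs in the stem
  pm <- pairing_map(h$structure)
  ch <- strsplit(h$sequence, "")[[1]]
  gu <- 0
  for (i in which(!is.na(pm) & seq_along(pm) < pm)) {
    a <- ch[i]; b <- ch[pm[i]]
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) gu <- gu + 1
  }
  expect_equal(gu, 2)
})

test_that("folding a bulged template recovers the designed duplex", {
  h <- make_hairpin(22, 3, 0, 1, "5p", seed = 7)
  f <- fold_candidate(h$sequence, 10)
  pm_engine <- pairing_map(f$structure[1])
  pm_design <- pairing_map(h$structure)
  mpos <- (h$mature_span[1] + 1):h$mature_span[2]
  expect_equal(pm_engine[mpos], pm_design[mpos])
})

test_that("mature cannot fit in a short stem", {
  expect_error(make_hairpin(21, 6, 0, 0, "3p", 1), "mature cannot fit")
})

test_that("evolve_family respects zero and region-restricted rates", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 3)
  tree <- "(A:50,B:50);"
  zero <- c(five_prime = 0, mir_star = 0, loop = 0, mir = 0, three_prime = 0)
  fam <- evolve_family(h, tree, zero, seed = 4)
  expect_true(all(fam$tips == h$sequence))
  loop_only <- zero
  loop_only["loop"] <- 0.01
  fam2 <- evolve_family(h, tree, loop_only, seed = 5)
  part <- partition_regions(h)
  loop_cols <- (part$spans$loop[1] + 1):part$spans$loop[2]
  anc <- strsplit(h$sequence, "")[[1]]
  for (tip in fam2$tips) {
    diffcols <- which(strsplit(tip, "")[[1]] != anc)
    expect_true(all(diffcols %in% loop_cols))
  }
  expect_identical(evolve_family(h, tree, loop_only, seed = 5)$tips,
                   fam2$tips)
})

test_that("evolve_family validates inputs", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 3)
  r <- c(five_prime = 0.001, mir_star = 0.001, loop = 0.001, mir = 0.001,
         three_prime = -0.001)
  expect_error(evolve_family(h, "(A:50,B:50);", r, 1), "negative")
  r["three_prime"] <- 0.001
  expect_error(evolve_family(h, "(A:50,B:30);", r, 1), "ultrametric")
  expect_error(evolve_family(h, "(A:50,B:50);", r[-1], 1), "five regions")
})

test_that("pairwise divergence matches the Jukes-Cantor closed form", {
  # two tips, one shared rate, expected diffs/site = 3/4 (1 - e^(-8kT/3))
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 6)
  n <- nchar(h$sequence)
  T <- 10
  for (k in c(0.001, 0.005, 0.02)) {
    rates <- c(five_prime = k, mir_star = k, loop = k, mir = k,
               three_prime = k)
    p <- vapply(1:200, function(s) {
      fam <- evolve_family(h, sprintf("(A:%d,B:%d);", T, T), rates,
                           seed = s)
      a <- strsplit(fam$tips[["A"]], "")[[1]]
      b <- strsplit(fam$tips[["B"]], "")[[1]]
      mean(a != b)
    }, numeric(1))
    expected <- 0.75 * (1 - exp(-4 / 3 * 2 * k * T))
    se <- sd(p) / sqrt(length(p))
    expect_lt(abs(mean(p) - expected), 3 * se + 1e-12)
  }
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(42)
  for (rep in 1:10) {
    h <- make_hairpin(25 + rep, 5, 2, 0, "3p", seed = rep)
    s <- dinuc_shuffle(h$sequence)
    dinucs <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1]))
    }
    expect_identical(dinucs(s), dinucs(h$sequence))
    expect_identical(substr(s, 1, 1), substr(h$sequence, 1, 1))
  }
})

test_that("plant_genome places loci exactly and records truth", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 9)
  gen <- plant_genome(list(h), bg_len = 10000, seed = 3)
  loci <- gen$truth$planted_loci
  expect_equal(nrow(loci), 1)
  g <- gen$genome[[loci$contig[1]]]
  expect_equal(nchar(g), 10000)
  slice <- substr(g, loci$start[1] + 1, loci$end[1])
  expect_identical(if (loci$strand[1] == "-") revcomp(slice) else slice,
                   h$sequence)
  # mismatches are recorded
  gen2 <- plant_genome(list(h), list(list(template = h, n_mismatches = 3)),
                       bg_len = 10000, seed = 3)
  expect_setequal(gen2$truth$planted_loci$n_mismatches, c(0L, 3L))
  # overlap impossible -> error
  expect_error(plant_genome(list(h), bg_len = 50, seed = 1), "overlap")
})

test_that("a 4-mismatch copy is invisible to the scanner at max 3", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 10)
  gen <- plant_genome(list(), list(list(template = h, n_mismatches = 4)),
                      bg_len = 8000, seed = 11)
  hits <- scan_genome(setNames(mature_seq(h), "q"), gen$genome,
                      max_mismatches = 3)
  loci <- gen$truth$planted_loci
  # the star arm may still match; the mature region itself must not
  mature_lo <- loci$start[1] + h$mature_span[1]
  mature_hi <- loci$start[1] + h$mature_span[2]
  expect_false(any(hits$start < mature_hi & hits$end > mature_lo &
                     hits$strand == loci$strand[1]))
})

test_that("design_target_window reaches each half-step penalty exactly", {
  m <- "TTCCGAAGGGAGGTGTAGTGCA"
  for (p in seq(0, 3, by = 0.5))
    expect_equal(as.numeric(duplex_penalty(m, design_target_window(m, p))),
                 p)
  expect_identical(design_target_window(m, 0), oracle_revcomp(m))
  # no wobble-capable non-seed position -> half steps unreachable
  m2 <- "ACCCGACTGGACGACCACCACA"  # non-seed positions are A/C only
  expect_error(design_target_window(m2, 0.5), "closest achievable is 0")
  expect_error(design_target_window(m2, 2.5), "closest achievable is 2")
  expect_silent(design_target_window(m2, 2.0))
})

test_that("make_target_set emits families, orthologs and exact sites", {
  m <- c(miR1 = "TTCCGAAGGGAGGTGTAGTGCA", miR2 = "ACGGACTGTTACGAGCAAGCAT")
  ts <- make_target_set(2, c(3, 1), m,
                        planted = data.frame(mirna_idx = 2, family_idx = 1,
                                             member_idx = 1,
                                             designed_penalty = 2.0),
                        cds_len = 150, seed = 3)
  expect_equal(nrow(ts$families), 8)          # (3 + 1) genes x 2 species
  expect_setequal(unique(ts$families$species), c("spA", "spB"))
  expect_equal(sum(ts$families$family_id == "fam1"), 6)
  # planted in both species, recoverable at the exact designed score
  st <- ts$truth$planted_sites
  expect_equal(nrow(st), 2)
  for (i in seq_len(nrow(st))) {
    hits <- scan_cds(m[[st$mirna_id[i]]], ts$cds[[st$gene_id[i]]], 3.0)
    k <- which(hits$start == st$start[i])
    expect_length(k, 1)
    expect_equal(hits$expectation[k], 2.0)
  }
  # background scrubbed: no sub-3.0 site anywhere else
  for (gid in names(ts$cds)) for (mn in names(m)) {
    hits <- scan_cds(m[[mn]], ts$cds[[gid]], 3.0)
    for (j in seq_len(nrow(hits))) {
      ok <- any(st$gene_id == gid & st$mirna_id == mn &
                  st$start < hits$end[j] & hits$start[j] < st$end)
      expect_true(ok)
    }
  }
  # determinism
  expect_identical(make_target_set(2, c(3, 1), m,
                                   planted = data.frame(
                                     mirna_idx = 2, family_idx = 1,
                                     member_idx = 1, designed_penalty = 2.0),
                                   cds_len = 150, seed = 3)$cds, ts$cds)
})
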