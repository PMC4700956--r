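# region partition, difference counting, rate formula, group averaging,
# chronogram times

test_that("partition_regions tiles the precursor in the stated order", {
  p <- precursor("x", strrep("A", 130), strrep(".", 130),
                 mature_span = c(88L, 110L), star_span = c(10L, 32L),
                 arm = "three_prime")
  part <- partition_regions(p)
  expect_identical(names(part$spans),
                   c("five_prime", "mir_star", "loop", "mir", "three_prime"))
  expect_equal(part$spans$five_prime, c(0L, 10L))
  expect_equal(part$spans$mir_star, c(10L, 32L))
  expect_equal(part$spans$loop, c(32L, 88L))
  expect_equal(part$spans$mir, c(88L, 110L))
  expect_equal(part$spans$three_prime, c(110L, 130L))
  # mirror arm: mirrored order
  p5 <- precursor("y", strrep("A", 130), strrep(".", 130),
                  mature_span = c(10L, 32L), star_span = c(88L, 110L),
                  arm = "five_prime")
  expect_identical(names(partition_regions(p5)$spans),
                   c("five_prime", "mir", "loop", "mir_star", "three_prime"))
})

test_that("partition spans always tile [0, len)", {
  for (s in 1:25) {
    h <- make_hairpin(sample(22:40, 1), sample(3:12, 1), sample(0:3, 1),
                      sample(0:2, 1), sample(c("3p", "5p"), 1), seed = s)
    part <- partition_regions(h)
    lens <- vapply(part$spans, function(sp) sp[2] - sp[1], integer(1))
    expect_equal(sum(lens), nchar(h$sequence))
    # contiguous
    sp <- do.call(rbind, part$spans)
    expect_equal(sp[-1, 1], sp[-nrow(sp), 2], ignore_attr = TRUE)
  }
})

test_that("count_region_differences applies the gap-exclusion rule", {
  p <- precursor("r", strrep("A", 20), strrep(".", 20),
                 mature_span = c(14L, 17L), star_span = c(2L, 5L),
                 arm = "three_prime")
  part <- partition_regions(p)
  ref <- paste0(strrep("A", 8), "-", strrep("A", 12))   # gap col in loop
  mask <- project_partition(ref, part)
  expect_length(mask, 21)
  a <- paste0("AAAAAAAA", "-", "CCC", "AAAAAAAAA")
  b <- paste0("AAAAAAAA", "G", "GGG", "AAAAAAAAA")
  d <- count_region_differences(a, b, mask)
  expect_equal(unname(d["loop"]), 3)                    # gap col excluded
  expect_equal(sum(d), 3)
  expect_equal(sum(count_region_differences(a, a, mask)), 0)
  expect_error(count_region_differences("AC", "ACG", mask), "length")
  # all-gap column changes nothing
  a2 <- paste0(substr(a, 1, 5), "-", substr(a, 6, 21))
  b2 <- paste0(substr(b, 1, 5), "-", substr(b, 6, 21))
  mask2 <- project_partition(paste0(substr(ref, 1, 5), "-",
                                    substr(ref, 6, 21)), part)
  expect_equal(count_region_differences(a2, b2, mask2), d)
})

test_that("random row pairs match a per-column counting oracle", {
  set.seed(5)
  h <- make_hairpin(30, 8, 0, 0, "3p", seed = 40)
  part <- partition_regions(h)
  n <- nchar(h$sequence)
  mask <- project_partition(h$sequence, part)  # ungapped reference
  for (rep in 1:20) {
    a <- strsplit(mirevo:::rand_seq(n), "")[[1]]
    b <- strsplit(mirevo:::rand_seq(n), "")[[1]]
    gaps <- sample(n, 5)
    a[gaps[1:2]] <- "-"; b[gaps[3:5]] <- "-"
    got <- count_region_differences(paste(a, collapse = ""),
                                    paste(b, collapse = ""), mask)
    want <- setNames(integer(5), names(got))
    for (i in seq_len(n))
      if (a[i] != "-" && b[i] != "-" && a[i] != b[i])
        want[mask[i]] <- want[mask[i]] + 1L
    expect_equal(got, want)
  }
})

test_that("pairwise_rate implements the published formula", {
  expect_equal(pairwise_rate(2, 20, 22, 10), 2 / 22 / 20)
  expect_equal(pairwise_rate(0, 20, 22, 10), 0)
  expect_equal(pairwise_rate(11, 22, 22, 125), 0.002)
  expect_error(pairwise_rate(1, 22, 22, 0), "> 0")
  # JC correction inverts the expected saturation
  p <- 0.3
  expect_equal(pairwise_rate(30, 100, 100, 10, correct = TRUE),
               -0.75 * log(1 - 4 / 3 * 0.3) / 20)
  expect_true(is.na(pairwise_rate(80, 100, 100, 10, correct = TRUE)))
})

test_that("group averaging equals hand computation", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 50)
  part <- partition_regions(h)
  fam <- evolve_family(h, "((A:10,B:10):15,C:25);",
                       c(five_prime = 0.002, mir_star = 0.001, loop = 0.008,
                         mir = 0.0005, three_prime = 0.002), seed = 51)
  times <- times_from_chronogram("((A:10,B:10):15,C:25);")
  g <- precursor_group("g1", fam$tips,
                       setNames(names(fam$tips), names(fam$tips)),
                       setNames(rep(list(part), 3), names(fam$tips)), times)
  got <- group_region_rates(g)
  expect_equal(got$n_pairs, rep(3L, 5))
  # hand-average the three pairs
  mask <- project_partition(fam$tips[[g$reference]], part)
  lens <- vapply(names(part$spans),
                 function(r) mirevo:::span_len(part$spans[[r]]), integer(1))
  prs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  for (r in names(part$spans)) {
    vals <- vapply(prs, function(pr) {
      d <- count_region_differences(fam$tips[[pr[1]]], fam$tips[[pr[2]]],
                                    mask)
      d[[r]] / lens[[r]] / (2 * times[pr[1], pr[2]])
    }, numeric(1))
    expect_equal(got$mean_rate[got$region == r], mean(vals))
    expect_equal(got$sd[got$region == r], sd(vals))
  }
  # two members: mean equals the single pairwise rate
  g2 <- precursor_group("g2", fam$tips[1:2],
                        setNames(names(fam$tips)[1:2], names(fam$tips)[1:2]),
                        setNames(rep(list(part), 2), names(fam$tips)[1:2]),
                        times)
  got2 <- group_region_rates(g2)
  expect_equal(got2$n_pairs, rep(1L, 5))
  expect_false(any(is.na(got2$mean_rate)))
})

test_that("T = 0 pairs are excluded and counted", {
  h <- make_hairpin(30, 6, 0, 0, "3p", seed = 52)
  part <- partition_regions(h)
  tips <- c(A1 = h$sequence, A2 = h$sequence, B = h$sequence)
  times <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8, 0), 3, 3,
                  dimnames = list(c("A1", "A2", "B"), c("A1", "A2", "B")))
  g <- precursor_group("g", tips, c(A1 = "A", A2 = "A", B = "B"),
                       setNames(rep(list(part), 3), names(tips)), times)
  got <- group_region_rates(g)
  expect_equal(got$n_pairs, rep(2L, 5))
  expect_equal(got$n_excluded, rep(1L, 5))
})

test_that("chronogram times equal MRCA ages", {
  tm <- times_from_chronogram("((A:10,B:10):40,C:50);")
  expect_equal(tm["A", "B"], 10)
  expect_equal(tm["A", "C"], 50)
  expect_equal(tm["B", "C"], 50)
  expect_equal(tm, t(tm))
  expect_equal(diag(tm), c(A = 0, B = 0, C = 0))
  expect_error(times_from_chronogram("((A:10,B:12):40,C:50);"),
               "ultrametric")
})

test_that("chronogram times match a path-intersection oracle", {
  set.seed(8)
  for (rep in 1:10) {
    tr <- random_chronogram(sample(4:9, 1), 50)
    got <- times_from_chronogram(tr)
    want <- oracle_pair_times(tr)
    expect_equal(got[rownames(want), colnames(want)], want,
                 tolerance = 1e-8)
  }
})

test_that("true region-rate ordering is recovered on simulated families", {
  # well-separated rates, corrected estimator, long regions
  h <- make_hairpin(60, 20, 0, 0, "3p", seed = 60)
  rates <- c(five_prime = 0.004, mir_star = 0.001, loop = 0.012,
             mir = 0.0004, three_prime = 0.007)
  part <- partition_regions(h)
  tree <- mirevo:::default_chronogram()
  times <- times_from_chronogram(tree)
  ok <- vapply(1:40, function(s) {
    # three replicate loci per trial, as in a multi-member precursor group
    est <- rowMeans(vapply(1:3, function(r) {
      fam <- evolve_family(h, tree, rates, seed = 3000 + 3 * s + r)
      g <- precursor_group("g", fam$tips,
                           setNames(names(fam$tips), names(fam$tips)),
                           setNames(rep(list(part), 8), names(fam$tips)),
                           times)
      e <- group_region_rates(g, correct = TRUE)
      setNames(e$mean_rate, e$region)
    }, numeric(5)))
    identical(rank(est), rank(rates[names(est)]))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("align_pair produces a sane global alignment", {
  al <- align_pair("ACGTACGT", "ACGACGT")
  expect_equal(nchar(al$a), nchar(al$b))
  expect_identical(gsub("-", "", al$a), "ACGTACGT")
  expect_identical(gsub("-", "", al$b), "ACGACGT")
  expect_equal(al$score, 7 - 2)            # 7 matches, one gap
})
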