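test_that("chromosome counts partition the loci and find planted peaks", {
  loci <- make_loci(paste0("g", 1:5), c("chrA", "chrA", "chrA", "chrB", "chrB"),
                    start = 1:5 * 1000, end = 1:5 * 1000 + 500)
  tab <- chromosome_counts(loci)
  expect_equal(setNames(tab$count, tab$chromosome),
               c(chrA = 3L, chrB = 2L))
  expect_equal(sum(tab$count), nrow(loci))
  expect_equal(nrow(chromosome_counts(loci[0, ])), 0)
  scaf <- make_loci("g6", "scaffold_12", 100, 600)
  tab2 <- chromosome_counts(rbind(loci, scaf))
  expect_true("unplaced" %in% tab2$chromosome)
})

test_that("the generator's planted density peak is the argmax chromosome", {
  ds <- generate_dataset(sim_config(seed = 19, species = c(A = 80L),
                                    decoy_rate = 0))
  tab <- chromosome_counts(ds$loci)
  expect_equal(tab$chromosome[1], "A_Chr06")  # sorted by descending count
})

test_that("tandem clusters follow the gap criterion with transitive closure", {
  # three genes at 10 kb spacing: one cluster of 3
  loci <- make_loci(paste0("g", 1:3), "chr1",
                    start = c(100000, 115000, 130000),
                    end = c(104000, 119000, 134000))
  cl <- detect_tandem_clusters(loci, policy = cluster_policy(max_gap_bp = 250000))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$member_count, 3L)
  expect_equal(cl$members, "g1;g2;g3")
  expect_equal(cl$span_start, 100000)
  expect_equal(cl$span_end, 134000)
  # two genes 500 kb apart: no cluster
  far <- make_loci(c("a", "b"), "chr1", c(1e6, 1.5e6), c(1.004e6, 1.504e6))
  expect_equal(nrow(detect_tandem_clusters(far,
    policy = cluster_policy(max_gap_bp = 250000))), 0)
  # singleton chromosome: nothing reported
  expect_equal(nrow(detect_tandem_clusters(make_loci("x", "chr9", 5, 10))), 0)
})

test_that("the intervening-gene criterion can break a distance link", {
  fam <- make_loci(c("f1", "f2"), "chr1", c(100000, 200000), c(105000, 205000))
  inter <- make_loci(paste0("n", 1:3), "chr1",
                     start = c(120000, 140000, 160000),
                     end = c(125000, 145000, 165000))
  all_loci <- rbind(fam, inter)
  pol_loose <- cluster_policy(max_gap_bp = 250000, max_intervening = 8)
  pol_tight <- cluster_policy(max_gap_bp = 250000, max_intervening = 2)
  expect_equal(detect_tandem_clusters(fam, all_loci, pol_loose)$member_count, 2L)
  expect_equal(nrow(detect_tandem_clusters(fam, all_loci, pol_tight)), 0)
  expect_error(detect_tandem_clusters(fam, inter, pol_loose), "missing family")
})

test_that("detected clusters agree with a brute-force closure oracle", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    starts <- sort(sample(1:2e6, n))
    loci <- make_loci(paste0("g", seq_len(n)),
                      sample(c("c1", "c2"), n, replace = TRUE),
                      start = starts, end = starts + sample(500:4000, n, TRUE))
    gap <- sample(c(5e4, 1e5, 2.5e5), 1)
    det <- detect_tandem_clusters(loci, policy = cluster_policy(max_gap_bp = gap))
    oracle <- brute_force_clusters(loci, gap)
    det_sets <- lapply(strsplit(det$members, ";"), sort)
    oracle_sets <- lapply(oracle, `[[`, "members")
    expect_setequal(vapply(det_sets, paste, "", collapse = ","),
                    vapply(oracle_sets, paste, "", collapse = ","))
  }
})

test_that("cluster membership partitions genes and spans never overlap", {
  set.seed(53)
  starts <- sort(sample(1:5e6, 40))
  loci <- make_loci(paste0("g", 1:40), "c1", starts, starts + 2000)
  cl <- detect_tandem_clusters(loci, policy = cluster_policy(max_gap_bp = 1e5))
  members <- unlist(strsplit(cl$members, ";"))
  expect_equal(anyDuplicated(members), 0)
  if (nrow(cl) > 1)
    expect_true(all(cl$span_start[-1] > cl$span_end[-nrow(cl)]))
})

test_that("raising the gap threshold never splits clusters", {
  set.seed(59)
  starts <- sort(sample(1:3e6, 25))
  loci <- make_loci(paste0("g", 1:25), "c1", starts, starts + 1500)
  gaps <- c(2e4, 5e4, 1e5, 3e5)
  prev <- NULL
  for (g in gaps) {
    cl <- detect_tandem_clusters(loci, policy = cluster_policy(max_gap_bp = g))
    sets <- lapply(strsplit(cl$members, ";"), identity)
    if (!is.null(prev)) {
      for (s in prev) {
        inside <- vapply(sets, function(x) all(s %in% x), TRUE)
        expect_true(any(inside))   # every old cluster survives intact
      }
    }
    prev <- sets
  }
})

test_that("terminal-arm fraction implements the midpoint rule", {
  lens <- c(chr1 = 1e6)
  near0 <- make_loci(paste0("g", 1:4), "chr1", c(1, 10, 100, 1000),
                     c(5, 20, 200, 2000))
  expect_equal(terminal_arm_fraction(near0, lens)$fraction, 1.0)
  centre <- make_loci("g1", "chr1", 499000, 501000)  # midpoint at 500 kb
  expect_equal(terminal_arm_fraction(centre, lens,
    cluster_policy(arm_fraction = 0.25))$fraction, 0.0)
  expect_error(terminal_arm_fraction(make_loci("g", "chrZ", 1, 2), lens),
               "chrZ")
})

test_that("terminal fraction is mirror-invariant and matches the binomial law", {
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  set.seed(61)
  n <- 10000
  chrom <- sample(names(lens), n, replace = TRUE)
  start <- floor(runif(n) * (lens[chrom] - 3000)) + 1
  loci <- make_loci(paste0("g", 1:n), chrom, start, start + 2999)
  pol <- cluster_policy(arm_fraction = 0.25)
  res <- terminal_arm_fraction(loci, lens, pol)
  # uniform placement: P(terminal) = 2 x arm_fraction = 0.5
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(res$fraction - 0.5), 3 * se)
  mirrored <- loci
  mirrored$start <- lens[loci$chromosome] - loci$end + 1
  mirrored$end <- lens[loci$chromosome] - loci$start + 1
  expect_equal(terminal_arm_fraction(mirrored, lens, pol)$fraction,
               res$fraction)
})
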