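test_that("candidate filter admits proteins with passing DUF26 hits only", {
  hits <- rbind(
    domain_hits("p1", S_DOM, 30, 130, e_value = 1e-40, bit_score = 150,
                significant = TRUE),
    domain_hits("p2", S_DOM, 40, 140, e_value = 1e-30, bit_score = 120,
                significant = TRUE),
    domain_hits("p3", K_DOM, 300, 560, e_value = 1e-60, bit_score = 210,
                significant = TRUE))
  expect_equal(filter_crk_candidates(hits), c("p1", "p2"))
  expect_equal(filter_crk_candidates(hits[0, ]), character(0))
})

test_that("unflagged hits fall back to the E-value ceiling", {
  h <- domain_hits("pX", S_DOM, 10, 110, e_value = 0.05, bit_score = 20,
                   significant = NA)
  expect_equal(filter_crk_candidates(h), character(0))
  h$e_value <- 1e-5
  expect_equal(filter_crk_candidates(h), "pX")
  # a flagged non-significant hit is rejected regardless of E-value
  h2 <- domain_hits("pY", S_DOM, 10, 110, e_value = 1e-20, bit_score = 20,
                    significant = FALSE)
  expect_equal(filter_crk_candidates(h2), character(0))
})

test_that("candidate filter is monotone in the E-value ceiling", {
  set.seed(101)
  hits <- do.call(rbind, lapply(1:30, function(i)
    domain_hits(paste0("p", i), S_DOM, 10, 110,
                e_value = 10^runif(1, -10, 1), bit_score = 50,
                significant = NA)))
  thresholds <- 10^seq(-8, 0, length.out = 9)
  sets <- lapply(thresholds, function(t)
    filter_crk_candidates(hits, filter_policy(e_value_max = t)))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("InterPro cross-validation modes restrict candidates", {
  pf <- domain_hits(c("p1", "p2"), S_DOM, c(30, 30), c(130, 130),
                    e_value = 1e-40, bit_score = 150, significant = TRUE)
  ipr <- domain_hits("p1", S_DOM, 30, 130, e_value = 1e-40, bit_score = 0,
                     domain_accession = "IPR002902", significant = TRUE)
  both <- rbind(pf, ipr)
  expect_equal(filter_crk_candidates(both,
    filter_policy(interpro_mode = "either")), "p1")
  expect_equal(filter_crk_candidates(both,
    filter_policy(interpro_mode = "off")), c("p1", "p2"))
  expect_equal(filter_crk_candidates(both,
    filter_policy(interpro_mode = "both")), character(0))
  ipr2 <- domain_hits("p1", S_DOM, 30, 130, e_value = 1e-40, bit_score = 0,
                      domain_accession = "IPR038408", significant = TRUE)
  expect_equal(filter_crk_candidates(rbind(both, ipr2),
    filter_policy(interpro_mode = "both")), "p1")
})

test_that("overlap resolution keeps the best of a conflicting pair", {
  hits <- rbind(
    domain_hits("p", S_DOM, 30, 130, e_value = 1e-20, bit_score = 50),
    domain_hits("p", S_DOM, 100, 200, e_value = 1e-10, bit_score = 40))
  out <- resolve_overlaps(hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$bit_score, 50)
  expect_equal(out$start, 30L)
})

test_that("overlap resolution basics: single hit, disjoint hits, mixed ids", {
  one <- domain_hits("p", S_DOM, 30, 130)
  expect_equal(as.data.frame(resolve_overlaps(one)), as.data.frame(one))
  two <- rbind(domain_hits("p", K_DOM, 300, 560),
               domain_hits("p", S_DOM, 30, 130))
  out <- resolve_overlaps(two)
  expect_equal(out$start, c(30L, 300L))   # kept, sorted by start
  mixed <- rbind(domain_hits("a", S_DOM, 1, 50), domain_hits("b", S_DOM, 1, 50))
  expect_error(resolve_overlaps(mixed), "single protein")
})

test_that("overlap resolution is idempotent and yields disjoint output", {
  set.seed(7)
  for (rep in 1:25) {
    hits <- random_protein_hits(sample(2:8, 1))
    out <- resolve_overlaps(hits)
    if (nrow(out) > 1)
      expect_true(all(out$end[-nrow(out)] < out$start[-1]))
    again <- resolve_overlaps(out)
    expect_equal(as.data.frame(again), as.data.frame(out))
  }
})

test_that("survivors form a maximal disjoint subset containing the best hit", {
  # brute-force oracle at overlap_fraction = 0: enumerate all subsets
  # of pairwise-disjoint hits, keep the maximal ones (no dropped hit
  # can be added back), and check the greedy survivor set is among
  # them and includes the top-scoring hit
  disjoint <- function(h, idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1)) {
      i <- idx[a]; j <- idx[b]
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1
      if (ov > 0) return(FALSE)
    }
    TRUE
  }
  set.seed(13)
  for (rep in 1:15) {
    hits <- random_protein_hits(sample(3:6, 1))
    hits <- hits[!duplicated(hits[, c("start", "end")]), ]
    n <- nrow(hits)
    maximal <- list()
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (!disjoint(hits, idx)) next
      addable <- any(vapply(setdiff(seq_len(n), idx), function(k)
        disjoint(hits, c(idx, k)), TRUE))
      if (!addable) maximal[[length(maximal) + 1]] <- idx
    }
    surv <- resolve_overlaps(hits, overlap_fraction = 0)
    key <- function(df) paste(sort(paste(df$start, df$end, df$domain_name)),
                              collapse = "|")
    surv_key <- key(surv)
    oracle_keys <- vapply(maximal, function(idx)
      key(hits[idx, , drop = FALSE]), "")
    expect_true(surv_key %in% oracle_keys)
    top <- which.max(hits$bit_score)
    expect_true(any(surv$start == hits$start[top] &
                      surv$end == hits$end[top] &
                      surv$domain_name == hits$domain_name[top]))
  }
})

test_that("fragment merging bridges small gaps of the same domain only", {
  frag <- rbind(domain_hits("p", S_DOM, 30, 80, e_value = 1e-10, bit_score = 40),
                domain_hits("p", S_DOM, 90, 140, e_value = 1e-15, bit_score = 35))
  merged <- merge_fragmented(frag, max_gap = 15)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(30L, 140L))
  expect_equal(merged$bit_score, 40)      # better score kept
  expect_equal(merged$e_value, 1e-15)     # smaller E-value kept
  # gap is 90 - 80 - 1 = 9 > 5: unchanged
  expect_equal(nrow(merge_fragmented(frag, max_gap = 5)), 2)
  expect_equal(nrow(merge_fragmented(frag, max_gap = 0)), 2)  # disabled
  # different names never merge
  diff <- rbind(domain_hits("p", S_DOM, 30, 80),
                domain_hits("p", K_DOM, 85, 140))
  expect_equal(nrow(merge_fragmented(diff, max_gap = 1000)), 2)
})

test_that("architectures are start-ordered with validated coordinates", {
  hits <- rbind(domain_hits("p", "DUF3403", 400, 480),
                domain_hits("p", S_DOM, 30, 130),
                domain_hits("p", S_DOM, 150, 250))
  arch <- build_architecture(hits)
  expect_s3_class(arch, "crk_architecture")
  expect_equal(architecture_labels(arch),
               c(S_DOM, S_DOM, "DUF3403"))
  expect_error(build_architecture(hits, protein_length = 400), "beyond.*p|p")
  expect_error(build_architecture(hits[0, ]), "zero hits")
  single <- build_architecture(domain_hits("q", S_DOM, 10, 100))
  expect_equal(architecture_labels(single), S_DOM)
})
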