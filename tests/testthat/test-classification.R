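DASH <- "\u2013"

test_that("major signatures collapse consecutive runs only", {
  expect_equal(
    classify_major(toy_architecture(c(S_DOM, S_DOM, K_DOM, "DUF3403"))),
    paste(S_DOM, K_DOM, "DUF3403", sep = DASH))
  # alternating pattern keeps non-consecutive repeats
  expect_equal(
    classify_major(toy_architecture(c(K_DOM, S_DOM, K_DOM))),
    paste(K_DOM, S_DOM, K_DOM, sep = DASH))
  expect_equal(classify_major(toy_architecture(S_DOM)), S_DOM)
  expect_error(classify_major(toy_architecture(K_DOM)), "not a CRK")
})

test_that("major signature equals an independent run-length-collapse oracle", {
  oracle <- function(labels) {
    # hand-rolled collapse, independent of the implementation
    kept <- character(0)
    prev <- ""
    for (l in labels) {
      if (!identical(l, prev)) kept <- c(kept, l)
      prev <- l
    }
    paste(kept, collapse = DASH)
  }
  pool <- c(S_DOM, K_DOM, "DUF3403", "FYVE", "TauE")
  set.seed(5)
  for (i in 1:50) {
    labels <- c(S_DOM, sample(pool, sample(0:5, 1), replace = TRUE))
    labels <- sample(labels)
    if (!S_DOM %in% labels) labels <- c(labels, S_DOM)
    expect_equal(classify_major(toy_architecture(labels)), oracle(labels))
  }
})

test_that("subclass signatures keep every repeat in order", {
  expect_equal(classify_subclass(toy_architecture(c(S_DOM, S_DOM))),
               paste(S_DOM, S_DOM, sep = "__"))
  expect_equal(
    classify_subclass(toy_architecture(c(S_DOM, S_DOM, "DUF3403"))),
    paste(S_DOM, S_DOM, "DUF3403", sep = "__"))
  expect_equal(classify_subclass(toy_architecture(S_DOM)), S_DOM)
})

test_that("in-place duplication never changes scheme 1 but always changes scheme 2", {
  pool <- c(S_DOM, K_DOM, "DUF3403", "FYVE")
  set.seed(11)
  for (i in 1:25) {
    labels <- c(S_DOM, sample(pool, sample(1:4, 1), replace = TRUE))
    j <- sample(seq_along(labels), 1)
    dup <- append(labels, labels[j], after = j)   # consecutive repeat
    expect_equal(classify_major(toy_architecture(dup)),
                 classify_major(toy_architecture(labels)))
    expect_false(classify_subclass(toy_architecture(dup)) ==
                   classify_subclass(toy_architecture(labels)))
  }
})

test_that("equal subclass signatures imply equal major signatures", {
  pool <- c(S_DOM, K_DOM, "DUF3403", "FYVE")
  set.seed(23)
  archs <- replicate(60, {
    labels <- c(S_DOM, sample(pool, sample(0:4, 1), replace = TRUE))
    toy_architecture(sample(labels))
  }, simplify = FALSE)
  sub <- vapply(archs, classify_subclass, "")
  maj <- vapply(archs, classify_major, "")
  for (s in unique(sub))
    expect_length(unique(maj[sub == s]), 1)
})

test_that("nomenclature names follow the prefix/core/suffix grammar", {
  nm <- function(labels) as.character(classify_nomenclature(toy_architecture(labels)))
  expect_equal(nm(c(S_DOM, S_DOM, K_DOM)), "ddCRK")
  expect_equal(nm(S_DOM), "sdCRRSP")
  expect_equal(nm(c("FYVE", S_DOM, S_DOM, K_DOM)), "ddCRKF")
  expect_equal(nm(c(S_DOM, S_DOM, K_DOM, "Pkinase_fungal")), "ddCRdK")
  expect_equal(nm(c(S_DOM, S_DOM, S_DOM, S_DOM, K_DOM, "DUF3403")), "qdCRKD")
  expect_equal(nm(c("SugarTransporter", "SugarTransporter", S_DOM)),
               "sdCRRSPdS")
  # fungal kinase alone does not make a CRK core
  expect_equal(nm(c(S_DOM, "Pkinase_fungal")), "sdCRRSP")
})

test_that("DUF26 counts beyond four get an explicit numeric prefix, not a crash", {
  out <- classify_nomenclature(toy_architecture(c(rep(S_DOM, 5), K_DOM)))
  expect_equal(as.character(out), "5dCRK")
  expect_true(attr(out, "extended_prefix"))
  expect_equal(parse_nomenclature("5dCRK")$duf26_count, 5)
})

test_that("every catalog class name regenerates and the count is nineteen", {
  catalog <- nomenclature_class_catalog()
  names_out <- vapply(names(catalog), function(n)
    as.character(classify_nomenclature(toy_architecture(catalog[[n]]))), "")
  expect_equal(unname(names_out), names(catalog))
  expect_length(unique(names_out), 19)
})

test_that("parsing inverts generation on the catalog and on random architectures", {
  for (labels in nomenclature_class_catalog()) {
    arch <- toy_architecture(labels)
    name <- as.character(classify_nomenclature(arch))
    p <- parse_nomenclature(name)
    expect_equal(p$duf26_count, sum(labels == S_DOM))
    has_k <- any(labels %in% c(K_DOM, "Pkinase"))
    has_f <- "Pkinase_fungal" %in% labels
    expect_equal(p$core,
                 if (has_k && has_f) "CRdK" else if (has_k) "CRK" else "CRRSP")
  }
  expect_equal(parse_nomenclature("ddCRKF"),
               list(duf26_count = 2L, core = "CRK", suffixes = "F"))
  expect_equal(parse_nomenclature("sdCRRSP"),
               list(duf26_count = 1L, core = "CRRSP", suffixes = character(0)))
  expect_equal(parse_nomenclature("ddCRdK"),
               list(duf26_count = 2L, core = "CRdK", suffixes = character(0)))
  set.seed(31)
  decoys <- c("DUF3403", "FYVE", "PRIMA1")
  for (i in 1:40) {
    labels <- c(rep(S_DOM, sample(1:4, 1)),
                if (runif(1) < 0.6) K_DOM,
                if (runif(1) < 0.2) "Pkinase_fungal",
                sample(decoys, sample(0:2, 1)))
    labels <- sample(labels)
    name <- as.character(classify_nomenclature(toy_architecture(labels)))
    p <- parse_nomenclature(name)
    expect_equal(p$duf26_count, sum(labels == S_DOM))
    regen <- paste0(
      c("sd", "dd", "td", "qd")[p$duf26_count], p$core,
      paste(p$suffixes, collapse = ""))
    expect_equal(regen, name)
  }
  expect_error(parse_nomenclature("xxCRK"), "longest valid prefix")
  expect_error(parse_nomenclature("ddCRKZ"), "bad suffix")
})

test_that("topology labels are invisible to all three schemes", {
  plain <- toy_architecture(c(S_DOM, S_DOM, K_DOM))
  topo <- toy_architecture(c("SignalPeptide", S_DOM, "Transmembrane",
                             S_DOM, K_DOM))
  expect_equal(classify_major(topo), classify_major(plain))
  expect_equal(classify_subclass(topo), classify_subclass(plain))
  expect_equal(as.character(classify_nomenclature(topo)),
               as.character(classify_nomenclature(plain)))
})

test_that("bulk assignment is deterministic with stable first-appearance ids", {
  catalog <- major_class_catalog()
  archs <- lapply(seq_along(catalog), function(i)
    toy_architecture(catalog[[i]], protein_id = paste0("p", i)))
  asg <- assign_all(archs, species = "spA")
  expect_equal(nrow(asg), 11)
  expect_equal(length(unique(asg$major_class_id)), 11)
  expect_equal(asg$major_class_id, seq_len(11))  # first-appearance order
  expect_identical(asg, assign_all(archs, species = "spA"))
  expect_equal(nrow(assign_all(list())), 0)
  # decoy side metadata is recorded relative to the first DUF26
  row <- assign_all(list(toy_architecture(c("FYVE", S_DOM, K_DOM, "DUF3403"))))
  expect_equal(row$decoys, "FYVE@Nterm;DUF3403@Cterm")
})
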