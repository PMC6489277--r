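# a handcrafted one-group library over a known sequence, with every
# peptide at a chosen uniform weight, for threshold arithmetic
manual_library <- function(seq, label = "GHM:1", conservation = 0.9,
                           avg_cov = 100, members = sprintf("m%d", 1:5),
                           subfamily_counts = c(`2` = 4L),
                           ec_counts = c(`3.2.1.8` = 3L, `3.2.1.4` = 1L)) {
  pool <- build_pool(seq, peptide_params())
  peps <- stats::setNames(rep(conservation^2, data.table::uniqueN(pool$entries$peptide)),
                          sort(unique(pool$entries$peptide)))
  g <- structure(list(label = label, family = sub(":.*$", "", label),
                      peptides = peps, members = members,
                      meta_summary = list(subfamily = subfamily_counts,
                                          ec = ec_counts,
                                          tax_class = c(Bacteria = 5L)),
                      avg_covered_positions = avg_cov,
                      theoretical_max = sum(peps)),
                 class = "cupp_group")
  compile_library(list(g))
}

test_that("lookup records every library hit of the query's variants", {
  set.seed(61)
  s <- random_protein(80)
  lib <- manual_library(s)
  m <- lookup_peptides(s, lib)
  # brute-force scan: expand the query and intersect with the index
  qpool <- build_pool(s, peptide_params())
  expected <- qpool$entries[peptide %chin% lib$index$peptide]
  expect_setequal(paste(m$peptide, m$start),
                  paste(expected$peptide, expected$start))
  expect_true(all(m$label == "GHM:1"))
  # self-hit: every stored peptide present in the member is matched
  expect_setequal(unique(m$peptide), lib$index$peptide)
})

test_that("queries without library peptides return no matches", {
  set.seed(62)
  lib <- manual_library(random_protein(80))
  none <- lookup_peptides(strrep("WY", 30), lib)
  expect_equal(nrow(none), 0L)
  # shorter than the window: empty with a warning at predict level
  expect_warning(ann <- cupp_predict(
    data.table::data.table(protein_id = "tiny", sequence = "MKLV"), lib),
    "shorter")
  expect_equal(nrow(ann), 0L)
})

test_that("initial filtering enforces the absolute and relative floors", {
  set.seed(63)
  s <- random_protein(300)
  lib <- manual_library(s, conservation = 1)   # weights 1, tmax ~ n_peptides
  tmax <- lib$groups[["GHM:1"]]$theoretical_max
  # matches worth 4.9 < 5: rejected even though far above 1% of nothing
  m <- data.table::data.table(peptide = sprintf("FAKE%04d", 1:7),
                              start = 0:6, label = "GHM:1", family = "GHM",
                              weight = 0.7)
  expect_equal(nrow(initial_filter(m, lib)), 0L)
  # sum 9 >= 5 but below 1% of a large theoretical max: rejected
  stopifnot(tmax > 900)
  m2 <- data.table::data.table(peptide = sprintf("FAKE%04d", 1:9),
                               start = 0:8, label = "GHM:1", family = "GHM",
                               weight = 1)
  expect_equal(nrow(initial_filter(m2, lib)), 0L)
  # a training member passes in full mode
  m3 <- lookup_peptides(s, lib)
  expect_equal(initial_filter(m3, lib)$label, "GHM:1")
  # duplicate occurrences of one peptide count once in the sum
  m4 <- rbind(m2, data.table::data.table(peptide = sprintf("FAKE%04d", 1:9),
                                         start = 10:18, label = "GHM:1",
                                         family = "GHM", weight = 1))
  expect_equal(cupp:::.group_sums(m4)$sum_unique, 9)
})

test_that("fast mode additionally requires eight distinct start positions", {
  set.seed(64)
  lib <- manual_library(random_protein(40), conservation = 1)
  m <- data.table::data.table(peptide = sprintf("FAKE%04d", 1:7),
                              start = rep(0:6, 1), label = "GHM:1",
                              family = "GHM", weight = 1)
  # seven starts, sum 7 >= 5 and >= 1% of tmax (~924)... below 1%: bump
  # weights so only the position rule decides
  m$weight <- 2
  expect_equal(nrow(initial_filter(m, lib, mode = "full")), 1L)
  expect_equal(nrow(initial_filter(m, lib, mode = "fast")), 0L)
  m8 <- rbind(m, data.table::data.table(peptide = "FAKE9999", start = 7L,
                                        label = "GHM:1", family = "GHM",
                                        weight = 2))
  expect_equal(nrow(initial_filter(m8, lib, mode = "fast")), 1L)
})

test_that("the accumulation profile counts repeated occurrences", {
  m <- data.table::data.table(peptide = c("P", "P", "Q"),
                              start = c(0L, 10L, 4L),
                              label = "G", family = "F",
                              weight = c(0.5, 0.5, 0.25))
  acc <- cupp:::.accumulation(m, 20L, 8L)
  expect_equal(acc[1], 0.5)           # only P at start 0
  expect_equal(acc[5], 0.75)          # P(0) + Q(4)
  expect_equal(acc[11], 0.75)         # P(10) + Q(4) tail
  expect_equal(sum(acc), 8 * (0.5 + 0.5 + 0.25))
})

test_that("the minimum-domain-length filter needs 20 positions above 0.2", {
  # one matched peptide of weight 0.9 covers only 8 positions
  acc1 <- cupp:::.accumulation(
    data.table::data.table(peptide = "P", start = 0L, label = "G",
                           family = "F", weight = 0.9), 60L, 8L)
  expect_false(position_filter(acc1))
  # three non-overlapping peptides of weight 0.3 cover 24 positions > 0.2
  acc3 <- cupp:::.accumulation(
    data.table::data.table(peptide = c("P", "Q", "R"),
                           start = c(0L, 10L, 20L), label = "G",
                           family = "F", weight = 0.3), 60L, 8L)
  expect_true(position_filter(acc3))
  expect_false(position_filter(numeric(60)))
})

test_that("overlap resolution keeps domains with half their mass free", {
  mk <- function(label, frac, positions, value = 1) {
    acc <- numeric(100); acc[positions] <- value
    list(label = label, frac_of_max = frac, acc = acc)
  }
  # disjoint halves: both kept (multimodular)
  both <- resolve_overlaps(list(mk("A", 0.9, 1:40), mk("B", 0.5, 51:90)))
  expect_equal(both, c("A", "B"))
  # a duplicate of the winner has zero free mass
  dup <- resolve_overlaps(list(mk("A", 0.9, 1:40), mk("A2", 0.5, 1:40)))
  expect_equal(dup, "A")
  # 60/40 overlap: loser with 40% of its mass free is rejected,
  # one with 60% free is kept
  r1 <- resolve_overlaps(list(mk("A", 0.9, 1:50), mk("B", 0.5, 21:70)))
  expect_equal(r1, "A")                      # 20 of 50 free = 40%
  r2 <- resolve_overlaps(list(mk("A", 0.9, 1:50), mk("B", 0.5, 31:80)))
  expect_equal(r2, c("A", "B"))              # 30 of 50 free = 60%
  # exactly 50% free: kept (>= semantics)
  r3 <- resolve_overlaps(list(mk("A", 0.9, 1:50), mk("B", 0.5, 26:75)))
  expect_equal(r3, c("A", "B"))
  # processing order is by decreasing fraction of the theoretical max
  r4 <- resolve_overlaps(list(mk("A", 0.2, 1:40), mk("B", 0.8, 51:90)))
  expect_equal(r4, c("B", "A"))
})

test_that("range inference bridges small gaps and splits large ones", {
  acc <- numeric(700)
  acc[1:30] <- 1
  rng1 <- infer_ranges(acc, avg_covered_positions = 100)
  expect_equal(rng1, data.table::data.table(start = 0L, end = 30L))
  # two clusters 300 apart with threshold clamped to 200: split
  acc2 <- numeric(700); acc2[1:30] <- 1; acc2[331:360] <- 1
  rng2 <- infer_ranges(acc2, avg_covered_positions = 500)  # clamps to 200
  expect_equal(nrow(rng2), 2L)
  expect_equal(rng2$start, c(0L, 330L))
  # gap exactly equal to the threshold is bridged
  acc3 <- numeric(700); acc3[1:30] <- 1; acc3[231:260] <- 1  # gap 200
  rng3 <- infer_ranges(acc3, avg_covered_positions = 500)
  expect_equal(nrow(rng3), 1L)
  expect_equal(rng3, data.table::data.table(start = 0L, end = 260L))
  # the minimum clamp: avg below 50 still bridges gaps up to 50
  acc4 <- numeric(200); acc4[1:20] <- 1; acc4[61:80] <- 1    # gap 40
  expect_equal(nrow(infer_ranges(acc4, avg_covered_positions = 10)), 1L)
})

test_that("full-filtering assigns group, subfamily and majority EC", {
  set.seed(65)
  s <- random_protein(200)
  lib <- manual_library(s)
  ann <- cupp_predict(data.table::data.table(protein_id = "q", sequence = s),
                      lib, mode = "full")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$family, "GHM")
  expect_equal(ann$group_label, "GHM.1")
  expect_equal(ann$subfamily, 2L)
  # majority EC first, minority appended with "-"
  expect_equal(ann$ec, "3.2.1.8-3.2.1.4")
  expect_equal(ann$mode, "full")
  # the full span of the training sequence is covered
  rng <- as.integer(strsplit(ann$ranges, "[.;]")[[1]])
  expect_equal(rng, c(0L, 200L))
})

test_that("subfamily needs at least three members of the same subfamily", {
  set.seed(66)
  s <- random_protein(120)
  lib2 <- manual_library(s, subfamily_counts = c(`2` = 2L, `7` = 1L))
  ann2 <- cupp_predict(data.table::data.table(protein_id = "q", sequence = s),
                       lib2, mode = "full")
  expect_true(is.na(ann2$subfamily))
})

test_that("weak family hits get the 0.1 sentinel and no function", {
  set.seed(67)
  s <- random_protein(1000)
  lib <- manual_library(s, conservation = 1)
  tmax <- lib$groups[["GHM:1"]]$theoretical_max
  # a 45-residue fragment scores well below 5% of the full model
  frag <- substr(s, 101, 145)
  m <- lookup_peptides(frag, lib)
  frac <- sum(m$weight[!duplicated(m$peptide)]) / tmax
  expect_gt(frac, 0.01); expect_lt(frac, 0.05)
  ann <- cupp_predict(data.table::data.table(protein_id = "frag",
                                             sequence = frag), lib, "full")
  expect_equal(ann$group_label, "GHM.0.1")
  expect_true(is.na(ann$subfamily))
  expect_true(is.na(ann$ec))
})

test_that("fast mode assigns only the family-level double-zero label", {
  set.seed(68)
  s <- random_protein(150)
  lib <- manual_library(s)
  ann <- cupp_predict(data.table::data.table(protein_id = "q", sequence = s),
                      lib, mode = "fast")
  expect_equal(ann$group_label, "GHM.0.0")
  expect_equal(ann$ranges, "")
  expect_true(is.na(ann$subfamily))
  expect_true(is.na(ann$ec))
})

test_that("fast-filtering family hits contain the full-filtering hits", {
  pipe <- tiny_pipeline()
  queries <- pipe$rec$seq[seq(1, .N, by = 3)]
  full <- cupp_predict(queries, pipe$lib, "full")
  fast <- cupp_predict(queries, pipe$lib, "fast")
  full_hits <- unique(full[, .(query_id, family)])
  fast_hits <- unique(fast[, .(query_id, family)])
  expect_true(all(paste(full_hits$query_id, full_hits$family) %in%
                    paste(fast_hits$query_id, fast_hits$family)))
})

test_that("self-annotation recovers every training member's own group", {
  pipe <- tiny_pipeline()
  ann <- cupp_predict(pipe$rec, pipe$lib, "full")
  membership <- data.table::rbindlist(lapply(pipe$lib$groups, function(g)
    data.table::data.table(query_id = g$members,
                           expected = sub(":", ".", g$label))))
  j <- merge(ann, membership, by = "query_id")
  expect_equal(nrow(j), nrow(membership))
  expect_equal(j$group_label, j$expected)
})

test_that("annotation is independent of query order", {
  pipe <- tiny_pipeline()
  q <- pipe$rec$seq[1:6]
  a1 <- cupp_predict(q, pipe$lib)
  a2 <- cupp_predict(q[6:1], pipe$lib)
  expect_identical(a1, a2)
})

test_that("concatenated members of two families yield two domain calls", {
  md <- memo("multidomain", {
    specA <- synthetic_family_spec(n_groups = 2, members_per_group = 6,
                                   ancestor_length = 200,
                                   within_mutation_rate = 0.02,
                                   family = "GHA", seed = 71)
    specB <- synthetic_family_spec(n_groups = 2, members_per_group = 6,
                                   ancestor_length = 200,
                                   within_mutation_rate = 0.02,
                                   family = "GHB", seed = 72)
    md <- generate_multidomain(specA, specB, linker_length = 30)
    groups <- unlist(lapply(list(md$famA, md$famB), function(f) {
      rec <- family_records(f$seq, f$meta)
      finalize_family(run_incremental(rec), rec)
    }), recursive = FALSE)
    list(md = md, lib = compile_library(groups))
  })
  q <- md$md$seq[1:4]
  ann <- cupp_predict(q, md$lib, "full")
  for (qid in q$protein_id) {
    calls <- ann[query_id == qid]
    expect_equal(sort(unique(calls$family)), c("GHA", "GHB"))
    truth <- md$md$truth[protein_id == qid]
    for (f in c("GHA", "GHB")) {
      tr <- truth[family == f]
      rng <- calls[family == f]$ranges[1]
      parts <- as.integer(strsplit(rng, "[.;]")[[1]])
      lo <- parts[1]; hi <- parts[length(parts)]
      ov <- max(0, min(hi, tr$end) - max(lo, tr$start))
      expect_gte(ov / (tr$end - tr$start), 0.8)
    }
    # ranges of the two families' calls do not overlap
    spanA <- as.integer(strsplit(calls[family == "GHA"]$ranges[1], "[.;]")[[1]])
    spanB <- as.integer(strsplit(calls[family == "GHB"]$ranges[1], "[.;]")[[1]])
    expect_true(max(spanA) <= min(spanB) || max(spanB) <= min(spanA))
  }
})
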