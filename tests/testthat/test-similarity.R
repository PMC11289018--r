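test_that("edit_distance handles the canonical cases", {
  abc <- c("a", "b", "c")
  expect_equal(edit_distance(abc, abc), 0)
  expect_equal(edit_distance(abc, character(0)), 3)
  expect_equal(edit_distance(character(0), abc), 3)
  expect_equal(edit_distance(strsplit("kitten", "")[[1]],
                             strsplit("sitting", "")[[1]]), 3)
})

test_that("edit_distance matches the brute-force recursive oracle", {
  seqs3 <- all_seqs(c("a", "b", "c"), 3)
  for (a in seqs3) {
    for (b in seqs3) {
      expect_identical(edit_distance(a, b), brute_edit(a, b))
    }
  }
  # longer random pairs (recursion is exponential, so sample these)
  set.seed(41)
  for (rep in 1:60) {
    a <- sample(c("a", "b", "c"), sample(0:6, 1), replace = TRUE)
    b <- sample(c("a", "b", "c"), sample(0:6, 1), replace = TRUE)
    expect_identical(edit_distance(a, b), brute_edit(a, b))
  }
})

test_that("edit_sim normalizes by the longer sequence", {
  expect_equal(edit_sim(1:3, 1:3), 1)
  expect_equal(edit_sim(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_equal(edit_sim(c(1, 2, 3), c(1, 2)), 1 - 1 / 3)
  expect_error(edit_sim(numeric(0), numeric(0)), "empty")
})

test_that("ngrukkon compares interval n-gram profiles", {
  a <- melody(c(60, 62, 64, 65, 67))
  expect_equal(ngrukkon(a, a), 1)
  # no shared trigram: intervals (2,2,1,2) vs (1,1,1,1)
  b <- melody(c(60, 61, 62, 63, 64))
  expect_equal(ngrukkon(a, b), 0)
  # one shared trigram of two each: profiles {221:1, 212:1} vs {221:1, 213:1}
  d <- melody(c(60, 62, 64, 65, 68))
  expect_equal(ngrukkon(a, d), 1 - 2 / 4)
  expect_error(ngrukkon(melody(60), a), "at least 2")
})

test_that("ngrukkon falls back to shorter n for very short items", {
  a <- melody(c(60, 64, 67))   # 2 intervals
  b <- melody(c(62, 66, 69))   # same intervals, transposed
  expect_equal(ngrukkon(a, b, n = 3), 1)  # n falls back to 2
  expect_equal(ngrukkon(melody(c(60, 64)), melody(c(62, 66)), n = 3), 1)
})

test_that("fuzzify_durations buckets by log ratio to the median", {
  expect_equal(as.integer(fuzzify_durations(rep(0.4, 5))), rep(3L, 5))
  expect_equal(as.integer(fuzzify_durations(c(0.25, 0.5, 1.0))), c(2L, 3L, 4L))
  d <- c(0.2, 0.3, 0.55, 1.4)
  expect_equal(as.integer(fuzzify_durations(d * 7.3)),
               as.integer(fuzzify_durations(d)))
  expect_error(fuzzify_durations(numeric(0)), "empty")
  expect_error(fuzzify_durations(c(1, -1)), "> 0")
})

test_that("rhythfuzz is edit similarity over duration classes", {
  m <- melody(c(60, 62, 64), duration = c(0.5, 0.5, 1))
  expect_equal(rhythfuzz(m, m), 1)
  a1 <- arhythmic_melody(c(60, 64, 67, 65))
  a2 <- arhythmic_melody(c(52, 55, 50, 59))
  expect_equal(rhythfuzz(a1, a2), 1)  # equal-length arhythmic items
  # class strings (M, M, L) vs (M, L): one deletion over max length 3
  expect_equal(edit_sim(c("M", "M", "L"), c("M", "L")), 1 - 1 / 3)
  # through the median-relative fuzzifier: (M, M, L) vs (M, M) also differs
  # by one deletion (a two-note melody is always symmetric about its median,
  # so an (M, L) class string cannot arise from two notes)
  x <- melody(c(60, 60, 60), duration = c(0.5, 0.5, 0.8))
  y <- melody(c(60, 60), duration = c(0.5, 0.5))
  expect_equal(as.integer(fuzzify_durations(note_durations(x))), c(3L, 3L, 4L))
  expect_equal(rhythfuzz(x, y), 1 - 1 / 3)
})

test_that("implied harmony matches the key-profile oracle on triads", {
  expect_equal(implied_harmony(melody(c(60, 64, 67))), "C major")
  expect_equal(implied_harmony(melody(c(57, 60, 64))), "A minor")
  # transposing rotates every label
  m <- melody(c(60, 62, 64, 65, 67, 69, 71, 72), duration = rep(0.25, 8))
  base <- implied_harmony(m)
  up <- implied_harmony(transpose_melody(m, 7))
  expect_equal(up, gsub("^C", "G", base))
})

test_that("harmcore compares implied-harmony label sequences", {
  m <- melody(c(60, 62, 64, 65, 67, 69, 71, 72))
  expect_equal(harmcore(m, m), 1)
  c_seg <- melody(c(60, 64, 67))
  g_seg <- melody(c(67, 71, 74))
  expect_equal(harmcore(c_seg, g_seg), 0)  # one substitution over length 1
  # same-shift transposition leaves harmcore unchanged
  m2 <- melody(c(62, 64, 66, 67, 69, 71, 73, 74))
  expect_equal(harmcore(transpose_melody(m, 3), transpose_melody(m2, 3)),
               harmcore(m, m2))
})

test_that("opti3 combines the components with the published weights", {
  m <- random_melody(8)
  expect_equal(opti3(m, m)$opti3, 1)
  expect_equal(opti3(m, m, similarity_weights(normalize = FALSE))$opti3, 6.968)
  set.seed(51)
  a <- random_melody(9); b <- random_melody(7)
  res <- opti3(a, b)
  manual <- (3.027 * ngrukkon(a, b) + 2.502 * rhythfuzz(a, b) +
               1.439 * harmcore(a, b)) / (3.027 + 2.502 + 1.439)
  expect_equal(res$opti3, manual)
  expect_equal(opti3(a, b, similarity_weights(normalize = FALSE))$opti3,
               manual * 6.968)
})

test_that("similarity components are symmetric, bounded and transposition invariant", {
  set.seed(61)
  for (rep in 1:40) {
    a <- random_melody(); b <- random_melody()
    ab <- opti3(a, b); ba <- opti3(b, a)
    expect_equal(unlist(ab), unlist(ba), tolerance = 1e-12)
    expect_true(all(unlist(ab) >= 0 & unlist(ab) <= 1))
    k <- sample(-5:5, 1)
    expect_equal(ngrukkon(transpose_melody(a, k), b), ngrukkon(a, b))
    expect_equal(rhythfuzz(transpose_melody(a, k), b), rhythfuzz(a, b))
    expect_equal(harmcore(transpose_melody(a, k), transpose_melody(b, k)),
                 harmcore(a, b))
  }
})

test_that("expected opti3 degrades as simulated singing gets noisier", {
  set.seed(71)
  target <- melody(c(60, 62, 64, 65, 67, 69, 67, 65, 64, 62),
                   duration = rep(c(0.25, 0.5), 5))
  sds <- c(0, 50, 150, 400, 1000)
  dels <- c(0, 0.1, 0.2, 0.35, 0.5)
  mean_sim_sd <- vapply(sds, function(s) {
    mean(vapply(1:15, function(i) {
      r <- simulate_recall(target, singer_params(pitch_sd = s, p_delete = 0,
                                                 p_insert = 0, seed = 1000 + i))
      opti3(target, r)$opti3
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(sds, mean_sim_sd, method = "spearman"), -1)
  mean_sim_del <- vapply(dels, function(p) {
    mean(vapply(1:15, function(i) {
      r <- simulate_recall(target, singer_params(pitch_sd = 10, p_delete = p,
                                                 p_insert = 0, seed = 2000 + i))
      opti3(target, r)$opti3
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(dels, mean_sim_del, method = "spearman"), -1)
})
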