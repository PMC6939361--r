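test_that("the undecayed trace is exactly the sum of position-item bindings", {
  voc <- toy_vocab(dim = 512, n = 8)
  tg <- make_tagset("item", 512, 4, seed = 1)
  toks <- c("s01", "s02", "s03")
  tr <- encode_sequence(toks, voc, tg, gamma = 1, rho = 0)
  manual <- hrr_bind(tg$tags[, 1], voc[["s01"]]) +
    hrr_bind(tg$tags[, 2], voc[["s02"]]) +
    hrr_bind(tg$tags[, 3], voc[["s03"]])
  expect_identical(tr$vector, manual)
  expect_identical(tr$length, 3L)
  # linearity holds under decay weights too
  trd <- encode_sequence(toks, voc, tg, gamma = 0.8, rho = 0.3)
  w <- 0.8^(2:0) + 0.3^(0:2)
  manual_d <- w[1] * hrr_bind(tg$tags[, 1], voc[["s01"]]) +
    w[2] * hrr_bind(tg$tags[, 2], voc[["s02"]]) +
    w[3] * hrr_bind(tg$tags[, 3], voc[["s03"]])
  expect_lt(max(abs(trd$vector - manual_d)), 1e-9)
})

test_that("appending a token equals re-weighting the prefix trace", {
  voc <- toy_vocab(dim = 512, n = 8)
  tg <- make_tagset("item", 512, 5, seed = 2)
  toks <- c("s01", "s04", "s02", "s07")
  gamma <- 0.82; rho <- 0.35
  full <- encode_sequence(toks, voc, tg, gamma, rho)
  # decompose the prefix into recency/primacy parts and append the last item
  bindings <- lapply(1:4, function(i) hrr_bind(tg$tags[, i], voc[[toks[i]]]))
  rec3 <- Reduce(`+`, lapply(1:3, function(i) gamma^(3 - i) * bindings[[i]]))
  prim3 <- Reduce(`+`, lapply(1:3, function(i) rho^(i - 1) * bindings[[i]]))
  appended <- gamma * rec3 + prim3 + (1 + rho^3) * bindings[[4]]
  expect_lt(max(abs(full$vector - appended)), 1e-9)
})

test_that("empty and degenerate sequences follow the contract", {
  voc <- toy_vocab(dim = 128, n = 4)
  tg <- make_tagset("item", 128, 4, seed = 3)
  tr0 <- encode_sequence(character(0), voc, tg)
  expect_identical(tr0$length, 0L)
  expect_identical(tr0$vector, numeric(128))
  expect_identical(serial_recall(tr0, voc, tg), character(0))
  tr1 <- encode_sequence("s02", voc, tg, gamma = 1, rho = 0)
  r <- recall_item(tr1, 1, voc, tg)
  expect_identical(r$name, "s02")
  expect_equal(r$score, 1, tolerance = 1e-9)  # single unitary binding is lossless
  expect_error(encode_sequence(c("s01", "zz"), voc, tg), class = "vsbind_vocab_miss")
  expect_error(encode_sequence(sprintf("s%02d", c(1:4, 1)), voc, tg),
               class = "vsbind_capacity_error")
  expect_error(recall_item(tr1, 2, voc, tg), class = "vsbind_param_error")
  expect_error(encode_sequence("s01", voc, tg, gamma = 0), class = "vsbind_param_error")
  expect_error(encode_sequence("s01", voc, tg, rho = 1), class = "vsbind_param_error")
})

test_that("serial recall round-trips short lists at high dimension", {
  tg <- make_tagset("item", 1024, 5, seed = 4)
  ok <- 0
  for (s in 1:25) {
    voc <- hrr_vocabulary(sprintf("w%02d", 1:32), 1024, child_seed(4, "rt", s))
    set.seed(child_seed(4, "rt-tokens", s))
    toks <- sample(voc$names, 5, replace = TRUE)
    tr <- encode_sequence(toks, voc, tg, gamma = 1, rho = 0)
    if (identical(serial_recall(tr, voc, tg), toks)) ok <- ok + 1
  }
  expect_gte(ok, 24)
})

test_that("recall of an absent position cleans up to no-match", {
  tg <- make_tagset("item", 1024, 6, seed = 5)
  misses <- 0
  for (s in 1:25) {
    voc <- hrr_vocabulary(sprintf("w%02d", 1:32), 1024, child_seed(5, "sel", s))
    tr <- encode_sequence(voc$names[1:3], voc, tg, gamma = 1, rho = 0)
    r <- cleanup(hrr_unbind(tr$vector, tg$tags[, 6]), voc, threshold = 0.1)
    if (!r$matched) misses <- misses + 1
  }
  expect_gte(misses, 24)
})

test_that("cleanup top-score falls as load grows (crosstalk)", {
  tg <- make_tagset("item", 256, 8, seed = 6)
  mean_score <- vapply(c(2, 5, 8), function(L) {
    mean(vapply(1:40, function(s) {
      voc <- hrr_vocabulary(sprintf("w%02d", 1:32), 256, child_seed(6, "ct", s * 10 + L))
      set.seed(child_seed(6, "ct-tok", s * 10 + L))
      toks <- sample(voc$names, L, replace = TRUE)
      tr <- encode_sequence(toks, voc, tg, gamma = 1, rho = 0)
      mean(vapply(seq_len(L), function(k)
        recall_item(tr, k, voc, tg, threshold = -1)$score, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_score[1], mean_score[2])
  expect_gt(mean_score[2], mean_score[3])
})

test_that("primacy and recency weighting produces a U-shaped position curve", {
  tg <- make_tagset("item", 256, 7, seed = 7)
  n <- 150
  acc <- matrix(0, n, 3)  # positions 1, 4, 7
  for (s in 1:n) {
    voc <- hrr_vocabulary(sprintf("w%02d", 1:32), 256, child_seed(7, "spc", s))
    set.seed(child_seed(7, "spc-tok", s))
    toks <- sample(voc$names, 7, replace = TRUE)
    tr <- encode_sequence(toks, voc, tg, gamma = 0.82, rho = 0.35)
    for (j in 1:3) {
      p <- c(1, 4, 7)[j]
      acc[s, j] <- identical(recall_item(tr, p, voc, tg, threshold = -1)$name,
                             toks[p])
    }
  }
  rates <- colMeans(acc)
  expect_gte(rates[1], rates[2])  # primacy
  expect_gte(rates[3], rates[2])  # recency
})

test_that("cross-list intrusions respect shared ordinal position", {
  # two lists held in one buffer: unbinding position j releases both lists'
  # j-th items, so intrusions from the other list cluster at the same position
  tg <- make_tagset("item", 512, 4, seed = 8)
  same_pos <- numeric(0); other_pos <- numeric(0)
  for (s in 1:30) {
    voc <- hrr_vocabulary(sprintf("w%02d", 1:16), 512, child_seed(8, "conf", s))
    l1 <- voc$names[1:4]; l2 <- voc$names[5:8]
    m <- encode_sequence(l1, voc, tg, 1, 0)$vector +
      encode_sequence(l2, voc, tg, 1, 0)$vector
    rec <- hrr_unbind(m, tg$tags[, 2])
    same_pos <- c(same_pos, hrr_similarity(rec, voc[[l2[2]]]))
    other_pos <- c(other_pos, hrr_similarity(rec, voc[[l2[3]]]))
  }
  expect_gt(mean(same_pos), mean(other_pos) + 0.1)
})
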