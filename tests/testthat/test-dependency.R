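test_that("salience filtering reduces A-X^n-B to the adjacent code, bitwise", {
  voc <- hrr_vocabulary(c("A", "B", "X"), 512, seed = 1)
  it <- make_tagset("item", 512, 2, seed = 1)
  ab <- encode_chunk(filter_salient(c("A", "B"), c("A", "B")), voc, it)
  for (n in 0:5) {
    seqn <- c("A", rep("X", n), "B")
    expect_identical(encode_chunk(filter_salient(seqn, c("A", "B")), voc, it), ab)
  }
  expect_identical(filter_salient(c("A", "X", "X", "B"), c("A", "B")), c("A", "B"))
  expect_identical(filter_salient(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_identical(filter_salient(c("A", "X", "B"), c(1, 3)), c("A", "B"))
  expect_error(filter_salient(c("X", "X"), "A"), class = "vsbind_spec_error")
  expect_error(filter_salient(character(0), "A"), class = "vsbind_param_error")
})

test_that("a chunk is interrogable by item position", {
  voc <- hrr_vocabulary(c("A", "B", "C"), 1024, seed = 2)
  it <- make_tagset("item", 1024, 3, seed = 2)
  ch <- encode_chunk(c("A", "B"), voc, it)
  expect_identical(cleanup(hrr_unbind(ch, it$tags[, 2]), voc)$name, "B")
  expect_identical(cleanup(hrr_unbind(ch, it$tags[, 1]), voc)$name, "A")
  # probing an unused position yields no-match
  r <- cleanup(hrr_unbind(ch, it$tags[, 3]), voc, threshold = 0.1)
  expect_false(r$matched)
  single <- encode_chunk("A", voc, it)
  expect_identical(single, hrr_bind(it$tags[, 1], voc[["A"]]))
  expect_error(encode_chunk(character(0), voc, it), class = "vsbind_param_error")
  expect_error(encode_chunk(c("A", "B", "C", "A"), voc, it),
               class = "vsbind_capacity_error")
})

test_that("structure specs validate layouts", {
  expect_s3_class(structure_spec(list(c(1, 4), c(2, 3)), "nested"), "structure_spec")
  expect_s3_class(structure_spec(list(c(1, 3), c(2, 4)), "crossed"), "structure_spec")
  expect_error(structure_spec(list(c(1, 3), c(2, 4)), "nested"),
               class = "vsbind_spec_error")
  expect_error(structure_spec(list(c(1, 4), c(2, 3)), "crossed"),
               class = "vsbind_spec_error")
  expect_error(structure_spec(list(c(1, 2), c(2, 3))), class = "vsbind_spec_error")
  expect_error(structure_spec(list(c(3, 2))), class = "vsbind_spec_error")
  expect_error(structure_spec(list()), class = "vsbind_spec_error")
})

make_nested_fixture <- function(seed, dim = 1024) {
  list(voc = hrr_vocabulary(c("A1", "A2", "B1", "B2"), dim,
                            child_seed(seed, "nest-voc")),
       it = make_tagset("item", dim, 2, child_seed(seed, "nest-it")),
       ch = make_tagset("chunk", dim, 2, child_seed(seed, "nest-ch")))
}

test_that("nested encoding pairs outer and inner items as chunks", {
  f <- make_nested_fixture(3)
  sp <- structure_spec(list(c(1, 4), c(2, 3)), "nested")
  st <- encode_structure(c("A1", "A2", "B2", "B1"), sp, f$voc, f$it, f$ch)
  got <- unpack_structure(st, f$voc, f$it, f$ch)
  expect_identical(got$name, c("A1", "B1", "A2", "B2"))
  expect_identical(attr(got, "n_nomatch"), 0L)
  # the three printed key patterns
  full <- invert_key(compose_key(list(f$it, f$ch), c(item = 2, chunk = 1)))
  expect_identical(query_structure(st, full, f$voc)[[1]]$name, "B1")
  chunk1 <- invert_key(compose_key(f$ch, c(chunk = 1)))
  r1 <- query_structure(st, chunk1, f$voc, item_tags = f$it)
  expect_identical(vapply(r1, function(x) x$name, character(1)), c("A1", "B1"))
  item2 <- invert_key(compose_key(f$it, c(item = 2)))
  r2 <- query_structure(st, item2, f$voc, chunk_tags = f$ch)
  expect_identical(vapply(r2, function(x) x$name, character(1)), c("B1", "B2"))
})

test_that("crossed encoding uses the same mechanism and stays distinguishable", {
  f <- make_nested_fixture(4)
  toks <- c("A1", "A2", "B1", "B2")
  spx <- structure_spec(list(c(1, 3), c(2, 4)), "crossed")
  stx <- encode_structure(toks, spx, f$voc, f$it, f$ch)
  got <- unpack_structure(stx, f$voc, f$it, f$ch)
  expect_identical(got$name, c("A1", "B1", "A2", "B2"))
  spn <- structure_spec(list(c(1, 4), c(2, 3)), "nested")
  stn <- encode_structure(toks, spn, f$voc, f$it, f$ch)
  expect_lt(abs(hrr_similarity(stn$vector, stx$vector)), 0.5)
})

test_that("structure encoding is boundary-relative across timescales", {
  # the same chunk layout built from far-apart vs contiguous serial positions
  # decodes from bitwise-identical traces given the same filtered inputs
  f <- make_nested_fixture(5, dim = 512)
  voc <- hrr_vocabulary(c("A1", "B1", "A2", "B2", "X"), 512, child_seed(5, "ts"))
  near <- encode_structure(c("A1", "A2", "B2", "B1"),
                           structure_spec(list(c(1, 4), c(2, 3)), "nested"),
                           voc, f$it, f$ch)
  far <- encode_structure(c("A1", "X", "A2", "X", "B2", "X", "B1"),
                          structure_spec(list(c(1, 7), c(3, 5)), "nested"),
                          voc, f$it, f$ch)
  expect_identical(near$vector, far$vector)
})

test_that("degenerate and invalid structures follow the contract", {
  f <- make_nested_fixture(6, dim = 512)
  one <- encode_structure("A1", structure_spec(list(1)), f$voc, f$it, f$ch)
  expect_identical(one$vector,
                   hrr_bind(f$ch$tags[, 1], hrr_bind(f$it$tags[, 1], f$voc[["A1"]])))
  got <- unpack_structure(one, f$voc, f$it, f$ch)
  expect_identical(got$name, "A1")
  expect_identical(attr(got, "n_nomatch"), 3L)
  # empty (zero) trace: every slot is a no-match
  zero <- one; zero$vector <- numeric(512)
  expect_identical(nrow(unpack_structure(zero, f$voc, f$it, f$ch)), 0L)
  k <- invert_key(compose_key(list(f$it, f$ch), c(item = 1, chunk = 1)))
  expect_false(query_structure(zero, k, f$voc)[[1]]$matched)
  # contract errors
  expect_error(encode_structure("A1", structure_spec(list(c(1, 2))), f$voc,
                                f$it, f$ch), class = "vsbind_spec_error")
  kraw <- compose_key(list(f$it, f$ch), c(item = 1, chunk = 1))
  expect_error(query_structure(one, kraw, f$voc), class = "vsbind_state_error")
  kw <- invert_key(compose_key(make_tagset("word", 512, 2, 1), c(word = 1)))
  expect_error(query_structure(one, kw, f$voc), class = "vsbind_key_error")
  expect_error(query_structure(one, invert_key(compose_key(f$ch, c(chunk = 1))),
                               f$voc), class = "vsbind_key_error")
})

test_that("round-trip accuracy does not increase with item count", {
  dim <- 512
  acc <- vapply(c(2, 3), function(k) {
    hits <- 0; slots <- 0
    for (s in 1:20) {
      voc <- hrr_vocabulary(sprintf("w%02d", 1:16), dim, child_seed(7, "depth", s))
      it <- make_tagset("item", dim, k, child_seed(7, "depth-it", s))
      ch <- make_tagset("chunk", dim, k, child_seed(7, "depth-ch", s))
      set.seed(child_seed(7, "depth-tok", s))
      toks <- sample(voc$names, k * k, replace = TRUE)
      sp <- structure_spec(split(seq_len(k * k), rep(1:k, each = k)))
      st <- encode_structure(toks, sp, voc, it, ch)
      got <- unpack_structure(st, voc, it, ch, threshold = -1)
      for (r in seq_len(nrow(got))) {
        slots <- slots + 1
        want <- toks[sp$chunks[[got$chunk[r]]][got$item[r]]]
        hits <- hits + identical(got$name[r], want)
      }
    }
    hits / slots
  }, numeric(1))
  expect_gte(acc[1], acc[2])
})

test_that("accumulated grammar traces support familiarity judgements", {
  dim <- 1024
  wins <- 0
  n_seeds <- 20
  for (s in 1:n_seeds) {
    voc <- grammar_vocabulary(4, dim, child_seed(11, "fam", s))
    tag_seed <- child_seed(11, "fam-tags", s)
    dep <- function(g) encode_dependency(filter_salient(g$tokens, g$salient),
                                         voc, tag_seed)
    train <- gen_grammar_sequences("axb", 50, child_seed(11, "fam-train", s),
                                   n_families = 4, p_grammatical = 1)
    mem <- accumulate_grammar_trace(lapply(train, dep))
    gram <- gen_grammar_sequences("axb", 1, child_seed(11, "fam-g", s),
                                  n_families = 4, p_grammatical = 1)[[1]]
    ungr <- gen_grammar_sequences("axb", 1, child_seed(11, "fam-u", s),
                                  n_families = 4, p_grammatical = 0)[[1]]
    if (familiarity(dep(gram), mem) > familiarity(dep(ungr), mem)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins / n_seeds, 0.9)
  # identity and contract cases
  v <- hrr_random(64, 1)
  expect_identical(accumulate_grammar_trace(list(v)), v)
  expect_error(accumulate_grammar_trace(list(v), c(1, 2)),
               class = "vsbind_param_error")
  expect_error(accumulate_grammar_trace(list(v), -1), class = "vsbind_param_error")
})

test_that("mismatch to the accumulated trace decays as exemplars accrue", {
  dim <- 1024
  it <- make_tagset("item", dim, 2, seed = 12)
  mism <- matrix(0, 10, 3)  # after 5, 20, 45 exemplars
  for (s in 1:10) {
    voc <- grammar_vocabulary(4, dim, child_seed(12, "mm", s))
    ex <- gen_grammar_sequences("axb", 46, child_seed(12, "mm-train", s),
                                n_families = 4, p_grammatical = 1)
    chunks <- lapply(ex, function(g)
      encode_chunk(filter_salient(g$tokens, g$salient), voc, it))
    for (j in 1:3) {
      n <- c(5, 20, 45)[j]
      mem <- accumulate_grammar_trace(chunks[seq_len(n)])
      mism[s, j] <- 1 - familiarity(chunks[[n + 1]], mem)
    }
  }
  m <- colMeans(mism)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})
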