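test_that("potency weights are pinned to 1 at the least active query", {
  w <- potency_weights(data.frame(mol_id = c("a", "b", "c"),
                                  ic50 = c(100, 10, 1)))
  expect_equal(unname(w), c(1, 2, 3))
  expect_identical(min(w), 1.0)
  expect_equal(unname(potency_weights(data.frame(mol_id = letters[1:3],
                                                 ic50 = rep(5, 3)))),
               rep(1, 3))
  expect_equal(unname(potency_weights(data.frame(mol_id = "a", ic50 = 7))),
               1)
  expect_error(potency_weights(data.frame(mol_id = "a", ic50 = NA_real_)),
               "IC50")
  expect_error(potency_weights(data.frame(mol_id = "a", ic50 = -1)), "IC50")
})

test_that("consensus fusion reproduces the policy definitions", {
  q1 <- bit_fp(c(1, 2), "synth64")
  q2 <- bit_fp(c(2, 3), "synth64")
  qs <- list(a = q1, b = q2)
  expect_setequal(build_consensus("opti", qs)$fused$keys, c(1, 2, 3))
  expect_identical(build_consensus("pess", qs)$fused$keys, 2L)
  r <- build_consensus("real", qs)$fused$weights
  expect_equal(r[c("1", "2", "3")], c("1" = 0.5, "2" = 1.0, "3" = 0.5))
  # weighted fusion: q1 = {1} (w 1), q2 = {2} (w 3) -> 0.25 / 0.75
  k <- build_consensus("know",
                       list(a = bit_fp(1, "synth64"),
                            b = bit_fp(2, "synth64")),
                       potency = c(a = 1, b = 3))$fused$weights
  expect_equal(k[c("1", "2")], c("1" = 0.25, "2" = 0.75))
  expect_error(build_consensus("opti", list()), "empty")
  expect_error(build_consensus("opti", list(q1, bit_fp(1, "maccs166"))),
               "space")
  expect_error(build_consensus("know", qs), "potency")
  expect_error(build_consensus("single", qs), "exactly one")
  # 4-letter abbreviations and full names both resolve
  expect_identical(build_consensus("optimist", qs)$policy, "opti")
  expect_identical(build_consensus("Oppo", qs)$policy, "oppo")
})

test_that("cscore follows the per-policy scoring rules", {
  qs <- list(a = bit_fp(c(1, 2), "synth64"), b = bit_fp(c(2, 3), "synth64"))
  cand <- bit_fp(2, "synth64")
  oppo <- build_consensus("oppo", qs)
  expect_equal(cscore(oppo, cand),
               max(tanimoto_binary(qs$a, cand), tanimoto_binary(qs$b, cand)))
  # realist vs candidate {2}: x = {1:.5, 2:1, 3:.5}, y = {2:1} -> 1 / 1.5
  real <- build_consensus("real", qs)
  expect_equal(cscore(real, cand), 2 / 3)
  sing <- build_consensus("single", qs["a"])
  expect_equal(cscore(sing, qs$a), 1.0)
  expect_error(cscore(oppo, bit_fp(2, "maccs166")), "space")
})

test_that("policy algebra holds on random query sets", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(2:6, 1L)
    qs <- replicate(n, rand_fp("synth64"), simplify = FALSE)
    names(qs) <- paste0("q", seq_len(n))
    cand <- rand_fp("synth64")
    s_single <- vapply(qs, function(q)
      cscore(build_consensus("single", list(x = q)), cand), numeric(1))
    # opportunist = max over members, dominating every single query
    expect_equal(cscore(build_consensus("oppo", qs), cand), max(s_single))
    # set sandwich: pess keys within every query, every query within opti
    pk <- build_consensus("pess", qs)$fused$keys
    ok <- build_consensus("opti", qs)$fused$keys
    for (q in qs) {
      expect_true(all(pk %in% q$keys))
      expect_true(all(q$keys %in% ok))
    }
    # knowledgeable with equal potencies equals realist
    w <- stats::setNames(rep(1, n), names(qs))
    expect_equal(cscore(build_consensus("know", qs, w), cand),
                 cscore(build_consensus("real", qs), cand))
    # realist bit-mass conservation: N * sum(weights) = sum of key counts
    rw <- build_consensus("real", qs)$fused$weights
    expect_equal(sum(rw) * n,
                 sum(vapply(qs, function(q) length(q$keys), numeric(1))))
    # realist on N identical copies scores like the single query
    copies <- stats::setNames(rep(qs[1], n), paste0("c", seq_len(n)))
    expect_equal(cscore(build_consensus("real", copies), cand), s_single[[1]])
  }
})

test_that("all consensus policies collapse to the single query at N = 1", {
  set.seed(5)
  for (i in 1:40) {
    q <- list(x = rand_fp("synth64"))
    cand <- rand_fp("synth64")
    ref <- cscore(build_consensus("single", q), cand)
    for (p in c("oppo", "pess", "opti", "real"))
      expect_equal(cscore(build_consensus(p, q), cand), ref)
    expect_equal(cscore(build_consensus("know", q, c(x = 1)), cand), ref)
  }
})
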