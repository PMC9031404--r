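test_that("closure reaches exactly the generable types, in a firing order", {
  q <- eq2_system()
  cl <- closure(q)
  expect_setequal(cl$available, c("GC", "PC", "mC", "b1C"))
  expect_equal(cl$order, "r1")

  # forced transitive chain
  ch <- chain_system()
  cl <- closure(ch)
  expect_setequal(cl$available, c("a", "b", "c"))
  expect_equal(cl$order, c("r1", "r2"))

  # empty foodset: nothing fires
  cl0 <- closure(ch, foodset = character())
  expect_length(cl0$available, 0)
  expect_length(cl0$order, 0)

  expect_error(closure(q, subset = "r9"), "unknown reaction")
})

test_that("closure is monotone and idempotent on random systems", {
  for (s in 1:20) {
    q <- random_small_system(s * 17, if (s %% 2) "polymer" else "mind")
    cl <- closure(q)
    expect_true(all(q$foodset %in% cl$available))
    cl2 <- closure(q, foodset = cl$available)
    expect_setequal(cl2$available, cl$available)
    # every fired reaction had its reactants available before its position
    avail <- q$foodset
    for (rid in cl$order) {
      r <- q$reactions[[rid]]
      expect_true(all(unique(r$reactants) %in% avail))
      avail <- union(avail, r$products)
    }
  }
})

test_that("the RA criterion accepts foodset and product catalysts only", {
  q <- eq2_system()
  expect_true(is_reflexively_autocatalytic(q, "r1")$is_RA)

  # removing the catalysis edge breaks RA
  q2 <- reaction_system(q$types, unname(q$reactions), NULL, q$foodset)
  res <- is_reflexively_autocatalytic(q2, "r1")
  expect_false(res$is_RA)
  expect_equal(res$uncatalyzed, "r1")

  # mutual catalysis via each other's products
  res <- is_reflexively_autocatalytic(mutual_system(), c("r1", "r2"))
  expect_true(res$is_RA)
})

test_that("is_raf combines both criteria and certifies failures", {
  q <- eq2_system()
  res <- is_raf(q, "r1")
  expect_true(res$is_RA && res$is_F_generated && res$is_RAF)

  expect_false(is_raf(q, character())$is_RAF)

  # r2 alone: reactant produced only by the excluded r1
  ch <- chain_system()
  res <- is_raf(ch, "r2")
  expect_false(res$is_RAF)
  expect_equal(res$ungenerated, "r2")
  expect_true(is_raf(ch, c("r1", "r2"))$is_RAF)
})

test_that("maxRAF matches the definitional brute-force oracle", {
  for (s in 1:40) {
    q <- random_small_system(s * 31 + 7, if (s %% 2) "polymer" else "mind",
                             max_R = 10L)
    expect_equal(max_raf(q)$subset, oracle_max_raf(q), info = paste("seed", s))
  }
})

test_that("maxRAF handles the stated edge cases", {
  expect_equal(max_raf(eq2_system())$subset, "r1")
  # no catalysis at all: nothing survives
  q <- reaction_system(c("a", "b"), list(reaction("r1", "a", "b")),
                       NULL, "a")
  expect_length(max_raf(q)$subset, 0)
  expect_false(max_raf(q)$is_RAF)
})

test_that("maxRAF is invariant under reaction relabelling (iteration order)", {
  for (s in c(3, 11)) {
    q <- random_small_system(s * 101, "polymer")
    base <- max_raf(q)$subset
    for (k in 1:20) {
      sh <- shuffle_reaction_ids(q, seed = 1000 * s + k)
      got <- max_raf(sh$q)$subset
      expect_setequal(got, unname(sh$map[base]))
    }
  }
})

test_that("subRAF enumeration yields a union-closed poset with unique top", {
  expect_equal(all_sub_rafs(eq2_system()), list("r1"))
  # no-RAF system
  q0 <- parse_system("F: a\nr1: a -> b")
  expect_length(all_sub_rafs(q0), 0)
  expect_error(all_sub_rafs(random_small_system(1), limit = 2), "too large")

  for (s in c(5, 9, 22)) {
    q <- random_small_system(s * 13, "mind", max_R = 9L)
    subs <- all_sub_rafs(q)
    expect_setequal(vapply(subs, paste, "", collapse = "+"),
                    vapply(oracle_all_rafs(q), paste, "", collapse = "+"))
    if (length(subs)) {
      top <- max_raf(q)$subset
      expect_setequal(subs[[length(subs)]], top)
      for (i in seq_along(subs)) {
        expect_true(all(subs[[i]] %in% top))
        for (j in seq_along(subs)) {
          u <- union(subs[[i]], subs[[j]])
          expect_true(any(vapply(subs, setequal, TRUE, u)))
        }
      }
    }
  }
})

test_that("exhaustive irrRAFs are minimal and sampling finds a subset of them", {
  d <- build_clive_thera()
  q <- mind_to_system(d$client)
  irr <- irr_rafs(q, "exhaustive")
  expect_length(irr, 3)
  # irreducibility: removing any reaction leaves no RAF inside
  for (w in irr) {
    for (r in w) {
      expect_length(max_raf(q, subset = setdiff(w, r))$subset, 0)
    }
  }
  # single-reaction RAF is its own irrRAF
  expect_equal(irr_rafs(eq2_system(), "exhaustive"), list("r1"))

  expect_error(irr_rafs(q, "sampled"), "seed")
  exh_keys <- vapply(irr, paste, "", collapse = "+")
  for (seed in 1:50) {
    smp <- irr_rafs(q, "sampled", seed = seed, samples = 5)
    expect_true(all(vapply(smp, paste, "", collapse = "+") %in% exh_keys))
  }
})

test_that("co-RAF and union properties follow the definitions", {
  ch <- chain_system()
  expect_true(is_co_raf(ch, addition = "r2", base = "r1"))
  expect_error(is_co_raf(ch, addition = "r1", base = "r2"), "not a RAF")
  expect_error(is_co_raf(ch, addition = character(), base = "r1"), "non-empty")

  # an addition that is itself a RAF is not a co-RAF
  two <- parse_system(
    "F: a, b\nr1: a -> x\nr2: b -> y\ncat: a r1\ncat: b r2")
  expect_false(is_co_raf(two, addition = "r2", base = "r1"))

  # union of two disjoint RAFs is a RAF; union is idempotent
  expect_true(union_raf(two, "r1", "r2")$is_RAF)
  expect_setequal(union_raf(two, "r1", "r1")$subset, "r1")
  expect_error(union_raf(ch, "r2", "r1"), "not a RAF")

  d <- build_clive_thera()
  q <- mind_to_system(d$client)
  subs <- all_sub_rafs(q)
  for (i in seq_along(subs))
    for (j in seq_along(subs))
      expect_true(union_raf(q, subs[[i]], subs[[j]])$is_RAF)
})

test_that("adding a catalysis edge never destroys an existing RAF", {
  for (s in 1:10) {
    q <- random_small_system(s * 7 + 3, "mind")
    top <- max_raf(q)$subset
    if (!length(top)) next
    set.seed(s)
    extra <- data.frame(catalyst = sample(q$types, 1),
                        reaction = sample(names(q$reactions), 1))
    q2 <- reaction_system(q$types, unname(q$reactions),
                          rbind(q$catalysis, extra), q$foodset)
    expect_true(is_raf(q2, top)$is_RAF)
    expect_true(all(top %in% max_raf(q2)$subset))
  }
})
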