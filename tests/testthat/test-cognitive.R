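fixture_minds <- function() {
  a <- mind("A")
  a <- add_foodset_item(a, "x1", "seen once")
  a <- add_foodset_item(a, "x2", "innate reflex", provenance = "innate")
  a <- redescribe(a, c("x1", "x2"), catalyst = "x1", product = "d1")
  b <- mind("B")
  b <- add_foodset_item(b, "y1")
  list(a = a, b = b)
}

test_that("foodset additions respect the provenance partition", {
  m <- mind("C")
  m <- add_foodset_item(m, "GC", "got a D- in math")
  m <- add_foodset_item(m, "PC", "didn't get the job")
  expect_setequal(m$foodset, c("GC", "PC"))
  expect_length(m$derived, 0)
  expect_equal(m$items$GC$provenance, "individual")
  m2 <- add_foodset_item(m, "i1", provenance = "innate")
  expect_equal(m2$items$i1$provenance, "innate")
  expect_error(add_foodset_item(m, "GC"), "duplicate")
  expect_error(add_foodset_item(m, "z", provenance = "derived"), "redescribe")
  expect_error(add_foodset_item(m, "z", provenance = "social"), "transmit")
})

test_that("transmission lands in the target foodset with social provenance", {
  fm <- fixture_minds()
  b <- transmit(fm$a, "x1", fm$b)
  expect_true("x1" %in% b$foodset)
  expect_equal(b$items$x1$provenance, "social")
  expect_equal(b$items$x1$source_mind, "A")
  expect_equal(b$items$x1$source_item, "x1")

  # generational rule: derived in the source, foodset in the target,
  # origin-mind tag preserved
  b2 <- transmit(fm$a, "d1", fm$b, new_id = "d1B")
  expect_true("d1B" %in% b2$foodset)
  expect_false("d1B" %in% b2$derived)
  expect_equal(b2$items$d1B$origin_mind, "A")

  expect_error(transmit(fm$a, "zz", fm$b), "not present")
})

test_that("redescription creates a derived item with its producing reaction", {
  fm <- fixture_minds()
  a <- redescribe(fm$a, "x1", catalyst = "d1", product = "d2",
                  label = "a reinterpretation")
  expect_true("d2" %in% a$derived)
  expect_false("d2" %in% a$foodset)
  rid <- attr(a, "reaction_id")
  expect_equal(a$items$d2$reaction, rid)
  expect_equal(a$reactions[[rid]]$reactants, "x1")
  expect_true(any(a$catalysis$catalyst == "d1" & a$catalysis$reaction == rid))
  expect_error(redescribe(fm$a, "nope", "x1", "d9"), "missing")
  expect_error(redescribe(a, "x1", "x2", "d2"), "duplicate")
})

test_that("inhibition strictly decreases and support strictly increases impact", {
  fm <- fixture_minds()
  a <- refresh_rafs(fm$a)
  expect_true(length(a$impact) >= 1)
  lbl <- names(a$impact)[1]
  w0 <- a$impact[[lbl]]
  a1 <- declare_inhibition(a, "x2", lbl)
  expect_lt(a1$impact[[lbl]], w0)
  a2 <- declare_inhibition(a1, "x1", lbl)
  expect_lt(a2$impact[[lbl]], a1$impact[[lbl]])
  expect_gt(a2$impact[[lbl]], 0)
  a3 <- support_raf(a2, lbl)
  expect_gt(a3$impact[[lbl]], a2$impact[[lbl]])
  expect_error(declare_inhibition(a, "x1", "no-such-raf"), "unknown RAF")
  expect_error(declare_inhibition(a, "zz", lbl), "unknown item")
})

test_that("provenance chains ground derived items in the foodset", {
  fm <- fixture_minds()
  pc <- provenance_chain(fm$a, "d1")
  expect_true(pc$grounded)
  expect_setequal(pc$sources, c("x1", "x2"))
  expect_true(all(c("reactant", "catalyst") %in% pc$edges$role))
  # foodset item: trivial single-node DAG
  pc0 <- provenance_chain(fm$a, "x1")
  expect_equal(nrow(pc0$nodes), 1)
  expect_equal(nrow(pc0$edges), 0)
  expect_true(pc0$grounded)
})

test_that("mind_to_system projects X/R/C/F and drops annotations", {
  fm <- fixture_minds()
  a <- refresh_rafs(fm$a)
  a <- declare_inhibition(a, "x2", names(a$impact)[1])
  q <- mind_to_system(a)
  expect_s3_class(q, "raf_system")
  expect_setequal(q$types, names(a$items))
  expect_setequal(q$foodset, a$foodset)
  expect_equal(length(q$reactions), length(a$reactions))
  # empty mind gives an empty system with no RAF
  q0 <- mind_to_system(mind("E"))
  expect_length(q0$types, 0)
  expect_false(max_raf(q0)$is_RAF)
})

test_that("random minds satisfy partition and groundedness by construction", {
  for (s in 1:30) {
    n_items <- 6 + (s %% 8)
    nd <- round(n_items * 0.3)
    m <- random_mind(n_items, nd + s %% 3, catalysis_prob = 0.1,
                     derived_fraction = 0.3, seed = s)
    expect_setequal(union(m$foodset, m$derived), names(m$items))
    expect_length(intersect(m$foodset, m$derived), 0)
    for (dd in m$derived) expect_true(provenance_chain(m, dd)$grounded)
  }
  # derived_fraction = 0 gives an empty derived set
  m0 <- random_mind(6, 0, derived_fraction = 0, seed = 1)
  expect_length(m0$derived, 0)
  # fixed-seed reproducibility
  expect_identical(random_mind(10, 4, 0.1, 0.3, seed = 9),
                   random_mind(10, 4, 0.1, 0.3, seed = 9))
  expect_error(random_mind(10, 1, 0.1, 0.5, seed = 1), "infeasible")
})

test_that("dyad replay is deterministic and idempotent", {
  fm <- fixture_minds()
  d <- dyad(fm$a, fm$b)
  d <- dyad_event(d, "transmit", "A", list(item = "d1", to = "B"), step = "s1")
  d <- dyad_event(d, "react", "B", list(reactants = "d1", catalyst = "y1",
                                        product = "n1"), step = "s2")
  r1 <- replay(d)
  r2 <- replay(r1)
  expect_identical(r1$client, d$client)
  expect_identical(r1$therapist, d$therapist)
  expect_identical(r2$client, r1$client)
  expect_true("n1" %in% r1$therapist$derived)
  expect_error(dyad_event(d, "poke", "A", list()), "unknown event kind")
})

test_that("dyads serialize to the JSON session schema", {
  d <- build_clive_thera()
  doc <- jsonlite::fromJSON(dyad_to_json(d), simplifyVector = FALSE)
  expect_equal(doc$format_version, 1)
  expect_length(doc$minds, 2)
  expect_equal(length(doc$log), length(d$log))
  expect_setequal(unique(vapply(doc$log, `[[`, "", "kind")),
                  c("react", "reweight", "transmit", "add", "inhibit"))
})

test_that("mind DOT export distinguishes foodset from derived items", {
  fm <- fixture_minds()
  a <- refresh_rafs(fm$a)
  dot <- mind_to_dot(a)
  expect_match(dot, '"x1" \\[shape=doublecircle\\]')
  expect_match(dot, '"d1" \\[shape=ellipse\\]')
  expect_match(dot, "subgraph cluster")
})
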