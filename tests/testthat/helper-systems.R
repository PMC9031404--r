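# Small fixture systems, built in code, plus a definitional brute-force
# oracle written directly from the two RAF criteria. The oracle shares no
# code with the package's algorithms (no compiled form, no unmet-count
# closure) so that agreement between the two is a real certificate.

eq2_system <- function() {
  parse_system("F: GC, PC, mC\nr1: GC + PC -> b1C\ncat: mC r1")
}

chain_system <- function() {
  parse_system("F: a\nr1: a -> b\nr2: b -> c\ncat: a r1\ncat: b r2")
}

# two reactions, each catalyzed by the other's product
mutual_system <- function() {
  parse_system("F: f1, f2\nr1: f1 -> x\nr2: f2 -> y\ncat: y r1\ncat: x r2")
}

oracle_closure <- function(q, subset) {
  avail <- q$foodset
  rs <- q$reactions[subset]
  repeat {
    progressed <- FALSE
    for (r in rs) {
      if (all(unique(r$reactants) %in% avail) &&
          !all(unique(r$products) %in% avail)) {
        avail <- union(avail, r$products)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  sort(avail)
}

oracle_is_raf <- function(q, subset) {
  if (!length(subset)) return(FALSE)
  rs <- q$reactions[subset]
  prods <- unique(unlist(lapply(rs, `[[`, "products")))
  ra <- all(vapply(subset, function(rid) {
    cats <- q$catalysis$catalyst[q$catalysis$reaction == rid]
    any(cats %in% union(q$foodset, prods))
  }, TRUE))
  if (!ra) return(FALSE)
  avail <- oracle_closure(q, subset)
  all(vapply(rs, function(r) all(unique(r$reactants) %in% avail), TRUE))
}

oracle_all_rafs <- function(q) {
  rids <- names(q$reactions)
  n <- length(rids)
  out <- list()
  if (n == 0L) return(out)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in seq_len(2L^n - 1L)) {
    sub <- rids[bitwAnd(mask, bits) != 0L]
    if (oracle_is_raf(q, sub)) out[[length(out) + 1L]] <- sort(sub)
  }
  out
}

oracle_max_raf <- function(q) {
  sort(unique(unlist(oracle_all_rafs(q))))
}

# seeded random test system: subsampled binary polymer chemistry or the
# reaction system of a random cognitive network, |R| <= max_R
random_small_system <- function(seed, kind = c("polymer", "mind"),
                                max_R = 12L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "polymer") {
    p <- stats::runif(1, 0.02, 0.35)
    q <- binary_polymer_system(3, 2, p, seed = seed + 1000L)
    keep <- sample(names(q$reactions), sample(4:max_R, 1))
    subsystem(q, keep)
  } else {
    n_items <- sample(8:14, 1)
    nd <- round(n_items * 0.3)
    nr <- min(max_R, nd + sample(0:5, 1))
    m <- random_mind(n_items, nr, catalysis_prob = stats::runif(1, 0.05, 0.25),
                     derived_fraction = 0.3, seed = seed + 5L)
    mind_to_system(m)
  }
}

# relabel reactions with a seeded permutation prefix so that canonical
# (id-sorted) iteration order differs, returning the renamed system and the
# old -> new id map
shuffle_reaction_ids <- function(q, seed) {
  set.seed(seed)
  rids <- names(q$reactions)
  new_ids <- stats::setNames(
    paste0(sprintf("s%03d", sample(seq_along(rids))), "_", rids), rids)
  reactions <- lapply(q$reactions, function(r)
    reaction(new_ids[[r$id]], r$reactants, r$products))
  cat2 <- q$catalysis
  cat2$reaction <- unname(new_ids[cat2$reaction])
  list(q = reaction_system(q$types, unname(reactions), cat2, q$foodset),
       map = new_ids)
}
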