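#' @title Generators: the binary polymer model and random minds
#' @description
#' The binary polymer model is the classic toy chemistry for studying the
#' emergence of autocatalytic sets: types are all binary strings up to a
#' maximum length n, the foodset is the strings up to length t (default 2,
#' the monomers and dimers), reactions are all ligations a + b -> ab within
#' the length bound (cleavage is the same reaction read backwards and is not
#' represented separately), and each (type, reaction) pair independently
#' catalyses with probability p. As p grows the system crosses a sharp
#' threshold from containing no RAF to almost surely containing one.
#' @name generators
NULL

# Counter-based sub-seed so that replicate k of a run is reproducible in
# isolation: sub_seed(seed, k) depends only on (seed, k) and stays < 2^31.
sub_seed <- function(seed, counter) {
  (as.double(seed) * 1000003 + counter * 7919) %% 2147483647
}

all_binary_strings <- function(n) {
  unlist(lapply(seq_len(n), function(len) {
    apply(as.matrix(expand.grid(rep(list(c("0", "1")), len))), 1,
          paste, collapse = "")
  }))
}

#' Generate a binary polymer catalytic reaction system
#'
#' @param max_length maximum polymer length n (>= 2).
#' @param food_max_length foodset cutoff t: all strings of length <= t are
#'   food (default 2); must satisfy t <= n.
#' @param catalysis_prob probability p that a given (type, reaction) pair is
#'   a catalysis edge, sampled independently.
#' @param seed integer RNG seed (required; the generator is deterministic
#'   given the seed).
#' @return a [reaction_system()] with `2^(n+1) - 2` types and
#'   `sum over L of 2^L * (L - 1)` ligation reactions, ids `lig_<a>_<b>` for
#'   a + b -> ab.
#' @examples
#' q <- binary_polymer_system(4, catalysis_prob = 0.01, seed = 42)
#' max_raf(q)$is_RAF
#' @export
binary_polymer_system <- function(max_length, food_max_length = 2L,
                                  catalysis_prob, seed) {
  n <- as.integer(max_length)
  t <- as.integer(food_max_length)
  p <- catalysis_prob
  stopifnot(n >= 2L, t >= 1L, t <= n, p >= 0, p <= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))

  types <- all_binary_strings(n)
  food <- types[nchar(types) <= t]

  lhs_a <- character(); lhs_b <- character()
  for (la in seq_len(n - 1L)) {
    for (lb in seq_len(n - la)) {
      as_ <- types[nchar(types) == la]
      bs_ <- types[nchar(types) == lb]
      grid <- expand.grid(a = as_, b = bs_, stringsAsFactors = FALSE)
      lhs_a <- c(lhs_a, grid$a)
      lhs_b <- c(lhs_b, grid$b)
    }
  }
  rids <- paste0("lig_", lhs_a, "_", lhs_b)
  reactions <- mapply(function(id, a, b)
    reaction(id, c(a, b), paste0(a, b)),
    rids, lhs_a, lhs_b, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  # independent Bernoulli(p) over the full (type, reaction) grid
  n_pairs <- length(types) * length(rids)
  hit <- which(stats::runif(n_pairs) < p)
  catalysis <- data.frame(
    catalyst = types[((hit - 1L) %% length(types)) + 1L],
    reaction = rids[((hit - 1L) %/% length(types)) + 1L],
    stringsAsFactors = FALSE
  )
  reaction_system(types = types, reactions = reactions,
                  catalysis = catalysis, foodset = food)
}

#' RAF phase-transition experiment on the binary polymer model
#'
#' For each catalysis probability in `p_grid`, generates `replicates`
#' independent systems (each from a counter-derived sub-seed, so any single
#' replicate can be regenerated in isolation), runs [max_raf()] on each, and
#' records the fraction of replicates containing a RAF and the mean maxRAF
#' size. The endpoints are forced: at p = 0 nothing is catalysed and the
#' fraction is 0; at p = 1 every reaction reachable from the foodset
#' survives and the fraction is 1.
#'
#' @param max_length,food_max_length as in [binary_polymer_system()].
#' @param p_grid numeric vector of catalysis probabilities.
#' @param replicates systems per grid point.
#' @param seed master seed.
#' @param max_size_guard refuse runs with `max_length` above this (default 8)
#'   unless `override = TRUE`; likewise replicates above 100.
#' @param override lift the desk-scale bounds.
#' @return a data frame with one row per grid point: `p`, `replicates`,
#'   `raf_fraction`, `mean_maxraf_size`.
#' @export
phase_experiment <- function(max_length = 6L, food_max_length = 2L,
                             p_grid, replicates = 25L, seed,
                             max_size_guard = 8L, override = FALSE) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(p_grid >= 0), all(p_grid <= 1), replicates >= 1L)
  if (!override && (max_length > max_size_guard || replicates > 100L))
    stop("requested size exceeds the desk-scale bounds ",
         "(max_length <= ", max_size_guard, ", replicates <= 100); ",
         "pass override = TRUE to proceed")
  counter <- 0L
  rows <- lapply(p_grid, function(p) {
    found <- logical(replicates)
    sizes <- integer(replicates)
    for (k in seq_len(replicates)) {
      counter <<- counter + 1L
      q <- binary_polymer_system(max_length, food_max_length, p,
                                 seed = sub_seed(seed, counter))
      mx <- max_raf(q)
      found[k] <- mx$is_RAF
      sizes[k] <- length(mx$subset)
    }
    data.frame(p = p, replicates = replicates,
               raf_fraction = mean(found),
               mean_maxraf_size = mean(sizes))
  })
  do.call(rbind, rows)
}

#' Generate a random cognitive network
#'
#' Builds a valid [mind()] satisfying all structural invariants by
#' construction: the requested fraction of items is foodset-derived, each
#' derived item is created by a [redescribe()] call whose reactants and
#' catalyst predate it (so every derivation chain is grounded in the
#' foodset), and extra catalysis edges are sprinkled with probability
#' `catalysis_prob` per (item, reaction) pair. Foodset provenance is sampled
#' over innate and individual learning only — social provenance needs a real
#' source mind, which a standalone generator cannot certify.
#'
#' @param n_items total number of mental representations.
#' @param n_reactions number of reactions; must be at least the number of
#'   derived items implied by `derived_fraction` (extra reactions re-derive
#'   existing derived items along alternative routes).
#' @param catalysis_prob probability of each additional (item, reaction)
#'   catalysis edge.
#' @param derived_fraction fraction of items that are foodset-derived.
#' @param seed integer RNG seed (required).
#' @param id mind id.
#' @return a [mind()].
#' @export
random_mind <- function(n_items, n_reactions, catalysis_prob = 0.05,
                        derived_fraction = 0.3, seed, id = "rnd") {
  stopifnot(n_items >= 1L, derived_fraction >= 0, derived_fraction <= 1,
            catalysis_prob >= 0, catalysis_prob <= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  n_derived <- round(n_items * derived_fraction)
  n_food <- n_items - n_derived
  if (n_food < 1L)
    stop("infeasible parameters: at least one foodset item is required")
  if (n_reactions < n_derived)
    stop("infeasible parameters: ", n_derived, " derived items need at least ",
         n_derived, " reactions")
  if (n_derived == 0L && n_reactions > 0L)
    stop("infeasible parameters: reactions must produce derived items, ",
         "but derived_fraction = 0")

  m <- mind(id)
  food_ids <- sprintf("f%02d", seq_len(n_food))
  for (fid in food_ids)
    m <- add_foodset_item(m, fid, provenance = sample(c("individual", "innate"), 1L))

  derived_ids <- if (n_derived) sprintf("d%02d", seq_len(n_derived)) else character()
  for (j in seq_len(n_derived)) {
    pool <- names(m$items)
    k <- sample(1:min(3L, length(pool)), 1L)
    m <- redescribe(m, reactants = sample(pool, k), catalyst = sample(pool, 1L),
                    product = derived_ids[j])
  }
  for (j in seq_len(n_reactions - n_derived)) {
    # alternative derivation of an existing derived item
    target <- sample(derived_ids, 1L)
    pool <- setdiff(names(m$items), target)
    k <- sample(1:min(3L, length(pool)), 1L)
    rid <- sprintf("alt%02d", j)
    r <- reaction(rid, sample(pool, k), target)
    m$reactions[[rid]] <- r
    m$reactions <- m$reactions[order(names(m$reactions))]
    m$catalysis <- unique(rbind(m$catalysis, data.frame(
      catalyst = sample(pool, 1L), reaction = rid, stringsAsFactors = FALSE)))
  }
  if (catalysis_prob > 0 && length(m$reactions)) {
    items <- names(m$items)
    rids <- names(m$reactions)
    n_pairs <- length(items) * length(rids)
    hit <- which(stats::runif(n_pairs) < catalysis_prob)
    if (length(hit)) {
      m$catalysis <- unique(rbind(m$catalysis, data.frame(
        catalyst = items[((hit - 1L) %% length(items)) + 1L],
        reaction = rids[((hit - 1L) %/% length(items)) + 1L],
        stringsAsFactors = FALSE)))
    }
  }
  validate_mind(m)
  m
}
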