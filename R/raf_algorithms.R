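#' @title RAF detection on catalytic reaction systems
#' @description
#' A non-empty reaction subset R' of a catalytic reaction system
#' Q = (X, R, C, F) is a RAF (Reflexively Autocatalytic and F-generated set)
#' when it satisfies two criteria:
#'
#' 1. *Reflexively autocatalytic*: every reaction in R' is catalyzed by at
#'    least one type that is either produced by R' or present in the
#'    foodset F.
#' 2. *F-generated*: every reactant of every reaction in R' can be built up
#'    from F using only reactions of R' (i.e. lies in the foodset closure of
#'    R').
#'
#' Catalyst availability plays no role in the closure itself: the two
#' criteria are checked independently, and the F-generated criterion concerns
#' reactants only.
#'
#' The collection of all RAFs of a system is closed under union, so when any
#' RAF exists there is a unique maximal one (the maxRAF), computed here by
#' [max_raf()] with a polynomial-time interleaved-pruning reduction and
#' certifiable against the exhaustive enumeration in [all_sub_rafs()].
#' @name raf-detection
NULL

# Integer-indexed form of a system used by all algorithms in this file.
# Reactant/product multiplicity is irrelevant to RAF logic, so only distinct
# type indices are kept.
compile_system <- function(q) {
  tid <- stats::setNames(seq_along(q$types), q$types)
  rids <- names(q$reactions)
  list(
    types = q$types,
    rids = rids,
    reactants = lapply(q$reactions, function(r) unname(tid[unique(r$reactants)])),
    products = lapply(q$reactions, function(r) unname(tid[unique(r$products)])),
    cats = if (length(rids)) {
      split(unname(tid[q$catalysis$catalyst]),
            factor(q$catalysis$reaction, levels = rids))
    } else list(),
    food = unname(tid[q$foodset])
  )
}

match_reactions <- function(cs, subset) {
  idx <- match(subset, cs$rids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(subset[is.na(idx)], collapse = ", "))
  sort(unique(idx))
}

# Foodset closure on the compiled form: least fixed point of "fire any
# reaction whose reactants are all available". Linear in edges via
# unmet-reactant counts.
closure_idx <- function(cs, sub, food = cs$food) {
  nT <- length(cs$types)
  nR <- length(sub)
  avail <- logical(nT)
  avail[food] <- TRUE
  need <- integer(nR)
  needers <- vector("list", nT)
  for (k in seq_len(nR)) {
    missing <- cs$reactants[[sub[k]]]
    missing <- missing[!avail[missing]]
    need[k] <- length(missing)
    for (t in missing) needers[[t]] <- c(needers[[t]], k)
  }
  fired <- logical(nR)
  queue <- which(need == 0L)
  order <- integer(0)
  while (length(queue)) {
    k <- queue[[1L]]
    queue <- queue[-1L]
    if (fired[k]) next
    fired[k] <- TRUE
    order <- c(order, k)
    new_types <- cs$products[[sub[k]]]
    new_types <- new_types[!avail[new_types]]
    for (t in new_types) {
      avail[t] <- TRUE
      for (j in needers[[t]]) {
        need[j] <- need[j] - 1L
        if (need[j] == 0L && !fired[j]) queue <- c(queue, j)
      }
    }
  }
  list(avail = avail, order = sub[order], fired = fired)
}

#' Foodset closure of a reaction subset
#'
#' Starting from the foodset, repeatedly adds the products of any reaction in
#' `subset` whose reactants are all currently available, until nothing more
#' can be added. Catalyst availability is deliberately not required: closure
#' implements only the F-generated criterion's notion of reachability.
#'
#' @param q a [reaction_system()].
#' @param subset reaction ids to use (default: all reactions of `q`).
#' @param foodset starting type set (default: `q$foodset`).
#' @return a list with `available` (sorted type ids reachable from the
#'   foodset) and `order` (one admissible firing order over the reactions of
#'   `subset` that can fire; reactions whose reactants never become available
#'   are absent from `order`).
#' @examples
#' q <- parse_system("F: a\nr1: a -> b\nr2: b -> c")
#' closure(q)$available
#' @export
closure <- function(q, subset = names(q$reactions), foodset = q$foodset) {
  cs <- compile_system(q)
  sub <- match_reactions(cs, subset)
  bad <- setdiff(foodset, q$types)
  if (length(bad)) stop("unknown type(s) in foodset: ", paste(bad, collapse = ", "))
  cl <- closure_idx(cs, sub, food = match(foodset, q$types))
  list(available = cs$types[cl$avail], order = cs$rids[cl$order])
}

# Full certificate for a subset; cs may be passed to avoid recompilation.
raf_certify <- function(q, subset, cs = NULL) {
  if (is.null(cs)) cs <- compile_system(q)
  sub <- match_reactions(cs, subset)
  nT <- length(cs$types)

  prod_avail <- logical(nT)
  prod_avail[cs$food] <- TRUE
  if (length(sub)) prod_avail[unlist(cs$products[sub])] <- TRUE
  uncat <- sub[!vapply(sub, function(ri) any(prod_avail[cs$cats[[ri]]]), TRUE)]

  cl <- closure_idx(cs, sub)
  ungen <- sub[!vapply(sub, function(ri) all(cl$avail[cs$reactants[[ri]]]), TRUE)]

  is_ra <- length(uncat) == 0L
  is_fgen <- length(ungen) == 0L
  structure(list(
    subset = cs$rids[sub],
    is_RA = is_ra,
    is_F_generated = is_fgen,
    is_RAF = length(sub) > 0L && is_ra && is_fgen,
    closure = list(available = cs$types[cl$avail], order = cs$rids[cl$order]),
    uncatalyzed = cs$rids[uncat],
    ungenerated = cs$rids[ungen]
  ), class = "raf_result")
}

#' @export
print.raf_result <- function(x, ...) {
  cat("<raf_result> |R'| = ", length(x$subset),
      "; RA = ", x$is_RA, "; F-generated = ", x$is_F_generated,
      "; RAF = ", x$is_RAF, "\n", sep = "")
  if (length(x$subset)) cat("  subset: ", paste(x$subset, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Check the reflexive-autocatalysis criterion
#'
#' A subset R' is reflexively autocatalytic (RA) when every reaction in it is
#' catalyzed by at least one type that is in the foodset or produced by some
#' reaction of R'.
#'
#' @param q a [reaction_system()].
#' @param subset reaction ids.
#' @return a `raf_result` with the `is_RA` flag and the failing reactions in
#'   `uncatalyzed` (the F-generation fields are also populated for
#'   completeness).
#' @export
is_reflexively_autocatalytic <- function(q, subset) raf_certify(q, subset)

#' Test whether a reaction subset is a RAF
#'
#' `is_RAF` is true iff `subset` is non-empty, reflexively autocatalytic, and
#' F-generated (every reactant lies in [closure()] of the foodset under
#' `subset`).
#'
#' @inheritParams is_reflexively_autocatalytic
#' @return a `raf_result` certificate: `subset`, flags `is_RA`,
#'   `is_F_generated`, `is_RAF`, the `closure` used, and the offending
#'   reaction ids in `uncatalyzed` / `ungenerated`.
#' @export
is_raf <- function(q, subset) raf_certify(q, subset)

raf_ok_idx <- function(cs, sub, nT = length(cs$types)) {
  cl <- closure_idx(cs, sub)
  for (ri in sub) if (!all(cl$avail[cs$reactants[[ri]]])) return(FALSE)
  pa <- logical(nT)
  pa[cs$food] <- TRUE
  pa[unlist(cs$products[sub])] <- TRUE
  for (ri in sub) if (!any(pa[cs$cats[[ri]]])) return(FALSE)
  TRUE
}

#' Compute the maxRAF of a system
#'
#' Iteratively reduces the full reaction set to a fixed point: at each pass
#' the foodset closure W of the surviving reactions is computed, and every
#' reaction with a reactant outside W or with no catalyst inside W is deleted.
#' The surviving set is the unique maximal RAF (empty when the system contains
#' no RAF). The result is independent of reaction iteration order, and the
#' reduction is polynomial-time, in contrast to the exponential enumeration of
#' [all_sub_rafs()].
#'
#' @param q a [reaction_system()].
#' @param subset restrict the search to a reaction subset (default: all
#'   reactions); the result is then the maxRAF of the subsystem.
#' @return a `raf_result` certifying the surviving subset (with `is_RAF =
#'   FALSE` and empty `subset` when no RAF exists).
#' @export
max_raf <- function(q, subset = names(q$reactions)) {
  cs <- compile_system(q)
  sub <- match_reactions(cs, subset)
  repeat {
    if (!length(sub)) break
    cl <- closure_idx(cs, sub)
    keep <- vapply(sub, function(ri) {
      all(cl$avail[cs$reactants[[ri]]]) && any(cl$avail[cs$cats[[ri]]])
    }, TRUE)
    if (all(keep)) break
    sub <- sub[keep]
  }
  raf_certify(q, cs$rids[sub], cs)
}

canonical_subset_order <- function(subs) {
  if (!length(subs)) return(subs)
  keys <- vapply(subs, function(s) paste(sort(s), collapse = "\r"), "")
  subs <- lapply(subs[!duplicated(keys)], sort)
  keys <- keys[!duplicated(keys)]
  subs[order(lengths(subs), keys)]
}

#' Enumerate all subRAFs by brute force
#'
#' Scans all 2^|R| - 1 non-empty reaction subsets with the definitional RAF
#' check, independently of the [max_raf()] reduction — this is the package's
#' certification oracle. The returned collection, ordered by size then
#' lexicographically, forms a poset under set inclusion that is closed under
#' pairwise union and (when non-empty) has the maxRAF as its unique maximal
#' element.
#'
#' @param q a [reaction_system()].
#' @param limit refuse systems with more than this many reactions
#'   (default 14, i.e. at most 2^14 subsets).
#' @return list of character vectors (reaction-id sets), canonically sorted.
#' @export
all_sub_rafs <- function(q, limit = 14L) {
  n <- length(q$reactions)
  if (n > limit)
    stop("system too large for exhaustive enumeration (", n,
         " reactions > limit ", limit, ")")
  if (n == 0L) return(list())
  cs <- compile_system(q)
  nT <- length(cs$types)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  out <- vector("list", 64L)
  n_out <- 0L
  for (mask in seq_len(2L^n - 1L)) {
    sub <- which(bitwAnd(mask, bits) != 0L)
    if (raf_ok_idx(cs, sub, nT)) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- cs$rids[sub]
    }
  }
  canonical_subset_order(out[seq_len(n_out)])
}

#' Irreducible RAFs
#'
#' An irrRAF is a RAF that contains no smaller RAF. In `"exhaustive"` mode the
#' minimal elements of the full subRAF poset are returned (subject to the
#' [all_sub_rafs()] size limit). In `"sampled"` mode, repeated random
#' shrinkage walks are performed from the maxRAF: remove a random reaction,
#' recompute the maxRAF inside the remainder, and keep shrinking until
#' removing any single reaction leaves no RAF. Sampling may miss irrRAFs but
#' every set returned is irreducible; results are deduplicated and a `seed`
#' is mandatory in this mode.
#'
#' @param q a [reaction_system()].
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param seed integer RNG seed (sampled mode only, required).
#' @param samples number of shrinkage walks in sampled mode.
#' @param limit exhaustive-mode size cap, as in [all_sub_rafs()].
#' @return list of character vectors, canonically sorted.
#' @export
irr_rafs <- function(q, mode = c("exhaustive", "sampled"), seed = NULL,
                     samples = 50L, limit = 14L) {
  mode <- match.arg(mode)
  if (mode == "exhaustive") {
    subs <- all_sub_rafs(q, limit = limit)
    minimal <- vapply(seq_along(subs), function(i) {
      !any(vapply(subs, function(s)
        length(s) < length(subs[[i]]) && all(s %in% subs[[i]]), TRUE))
    }, TRUE)
    return(subs[minimal])
  }
  if (is.null(seed)) stop("sampled mode requires a seed")
  set.seed(as.integer(seed))
  top <- max_raf(q)$subset
  if (!length(top)) return(list())
  found <- list()
  for (s in seq_len(samples)) {
    w <- top
    repeat {
      shrunk <- FALSE
      for (r in sample(w)) {
        cand <- max_raf(q, subset = setdiff(w, r))$subset
        if (length(cand)) {
          w <- cand
          shrunk <- TRUE
          break
        }
      }
      if (!shrunk) break
    }
    found[[length(found) + 1L]] <- w
  }
  canonical_subset_order(found)
}

#' Test the co-RAF property
#'
#' A co-RAF (relative to a RAF `base`) is a non-empty reaction set that is not
#' itself a RAF but forms one when united with `base`.
#'
#' @param q a [reaction_system()].
#' @param addition candidate reaction ids; non-empty and disjoint from `base`.
#' @param base reaction ids forming a RAF of `q` (checked; error otherwise).
#' @return `TRUE` or `FALSE`.
#' @export
is_co_raf <- function(q, addition, base) {
  if (!is_raf(q, base)$is_RAF) stop("`base` is not a RAF")
  if (!length(addition)) stop("`addition` must be non-empty")
  if (length(intersect(addition, base)))
    stop("`addition` must be disjoint from `base`")
  !is_raf(q, addition)$is_RAF && is_raf(q, union(addition, base))$is_RAF
}

#' Union of two RAFs
#'
#' The union of any two RAFs of the same system is again a RAF (which is why
#' a unique maxRAF exists). Both inputs are checked; the certified union is
#' returned.
#'
#' @param q a [reaction_system()].
#' @param r1,r2 reaction-id vectors, each a RAF of `q`.
#' @return a `raf_result` for `union(r1, r2)` with `is_RAF = TRUE`.
#' @export
union_raf <- function(q, r1, r2) {
  if (!is_raf(q, r1)$is_RAF) stop("`r1` is not a RAF")
  if (!is_raf(q, r2)$is_RAF) stop("`r2` is not a RAF")
  res <- is_raf(q, union(r1, r2))
  stopifnot(res$is_RAF)
  res
}

#' Full RAF analysis report
#'
#' Runs [max_raf()], [irr_rafs()] and (within the size cap) [all_sub_rafs()]
#' and assembles the JSON-ready report used by the command-line interface.
#'
#' @param q a [reaction_system()].
#' @param exhaustive_cap reaction-count cap for exhaustive enumeration; above
#'   it, irrRAFs are sampled and the subRAF count is omitted.
#' @param seed RNG seed used if sampling is needed.
#' @return a list: `maxRAF`, `irrRAFs`, `irrRAF_mode`, `subRAF_count` (NULL
#'   when skipped) and `certificates` for the maxRAF.
#' @export
raf_report <- function(q, exhaustive_cap = 14L, seed = 1L) {
  mx <- max_raf(q)
  exhaustive <- length(q$reactions) <= exhaustive_cap
  if (!exhaustive)
    message("system exceeds the exhaustive cap (", length(q$reactions), " > ",
            exhaustive_cap, "); sampling irrRAFs, subRAF count omitted")
  irr <- if (exhaustive) irr_rafs(q, "exhaustive", limit = exhaustive_cap)
         else irr_rafs(q, "sampled", seed = seed)
  subs <- if (exhaustive) all_sub_rafs(q, limit = exhaustive_cap)
  list(
    maxRAF = mx$subset,
    irrRAFs = irr,
    irrRAF_mode = if (exhaustive) "exhaustive" else "sampled",
    subRAF_count = if (exhaustive) length(subs),
    certificates = list(maxRAF = list(
      is_RA = mx$is_RA,
      is_F_generated = mx$is_F_generated,
      is_RAF = mx$is_RAF,
      closure_available = mx$closure$available,
      firing_order = mx$closure$order
    ))
  )
}
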