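#' @title Cognitive RAF networks
#' @description
#' In the cognitive instantiation of RAF theory, the entities are mental
#' representations (MRs) held by an individual mind i. The mind's *foodset*
#' F_i contains MRs that entered from outside its own creative processing:
#' innate knowledge, items learned socially from another mind, and items
#' acquired by individual (direct) experience. The *foodset-derived* set
#' holds MRs produced inside the mind by representational redescription (RR):
#' a catalysed "reaction" that combines or recodes existing MRs into a new
#' one. Foodset and derived items partition the mind's contents, and every
#' derived item carries the reaction that produced it, so its derivation can
#' be traced back to foodset items.
#'
#' Items also carry an origin-mind tag: when an item is socially transmitted,
#' the copy lands in the *receiving* mind's foodset (whatever its provenance
#' was for the sender), while the tag records whose mind it first arose in —
#' the generational rule by which one mind's creative products become another
#' mind's raw material.
#'
#' Inhibition and per-RAF impact weights annotate the network without
#' entering RAF detection: an inhibitory item (one inconsistent with a
#' belief cluster) multiplicatively weakens the impact weight of the RAF it
#' targets, and supporting events strengthen it; weights stay positive and
#' only their ordinal comparisons are meaningful.
#' @name cognitive-rafs
NULL

#' Create an empty mind
#'
#' @param id mind id token.
#' @param alpha multiplicative impact gain per supporting event (weight is
#'   multiplied by `1 + alpha`).
#' @param beta multiplicative impact loss per inhibition (weight is
#'   multiplied by `1 - beta`); must lie in (0, 1) so weights stay positive.
#' @return an object of class `raf_mind`.
#' @export
mind <- function(id, alpha = 0.5, beta = 0.5) {
  stopifnot(alpha > 0, beta > 0, beta < 1)
  structure(list(
    id = as.character(id),
    items = list(),
    foodset = character(),
    derived = character(),
    reactions = list(),
    catalysis = data.frame(catalyst = character(), reaction = character(),
                           stringsAsFactors = FALSE),
    inhibitions = data.frame(item = character(), raf = character(),
                             stringsAsFactors = FALSE),
    rafs = list(),
    impact = numeric(),
    alpha = alpha,
    beta = beta
  ), class = "raf_mind")
}

#' @export
print.raf_mind <- function(x, ...) {
  cat("<raf_mind> ", x$id, ": |X| = ", length(x$items),
      " (foodset ", length(x$foodset), ", derived ", length(x$derived),
      "), ", length(x$reactions), " reactions, ",
      length(x$rafs), " tracked RAF(s)\n", sep = "")
  invisible(x)
}

new_item <- function(id, label, origin_mind, provenance,
                     source_mind = NULL, source_item = NULL, reaction = NULL) {
  check_type_ids(id)
  list(id = id, label = label, origin_mind = origin_mind,
       provenance = provenance, source_mind = source_mind,
       source_item = source_item, reaction = reaction)
}

validate_mind <- function(m) {
  ids <- names(m$items)
  stopifnot(setequal(union(m$foodset, m$derived), ids),
            length(intersect(m$foodset, m$derived)) == 0L)
  for (it in m$items) {
    if (it$provenance == "derived") {
      stopifnot(it$id %in% m$derived, !is.null(it$reaction),
                it$reaction %in% names(m$reactions))
    } else {
      stopifnot(it$id %in% m$foodset,
                it$provenance %in% c("innate", "social", "individual"))
      if (it$provenance == "social")
        stopifnot(!is.null(it$source_mind), !is.null(it$source_item))
    }
  }
  stopifnot(all(m$impact > 0))
  invisible(m)
}

#' Add an innate or individually learned item to a mind's foodset
#'
#' Only innate and individual (direct-experience) provenance is allowed here;
#' socially learned items must arrive through [transmit()], and derived items
#' can only be produced by [redescribe()].
#'
#' @param m a [mind()].
#' @param id new item id (must be unused in `m`).
#' @param label free-text description.
#' @param provenance `"individual"` or `"innate"`.
#' @return the updated mind.
#' @export
add_foodset_item <- function(m, id, label = id,
                             provenance = "individual") {
  provenance <- match.arg(provenance, c("individual", "innate", "social", "derived"))
  if (provenance %in% c("social", "derived"))
    stop("provenance '", provenance, "' is not allowed here: use transmit() ",
         "for social items and redescribe() for derived items")
  if (id %in% names(m$items)) stop("duplicate item id: ", id)
  it <- new_item(id, label, origin_mind = m$id, provenance = provenance)
  m$items[[id]] <- it
  m$foodset <- sort(c(m$foodset, id))
  m
}

#' Socially transmit an item between minds
#'
#' A copy of `item` from `source` is added to `target`'s foodset with social
#' provenance, recording the source mind and item. The generational rule
#' applies: the copy is foodset in the receiver even if it was
#' foodset-derived in the sender, and the origin-mind tag is inherited, so
#' an idea's point of origin survives any number of retransmissions.
#'
#' @param source,target [mind()] objects.
#' @param item id of an item present in `source`.
#' @param new_id id for the copy in `target` (default: same id).
#' @param label label for the copy (default: the source item's label).
#' @return the updated `target` mind.
#' @export
transmit <- function(source, item, target, new_id = item, label = NULL) {
  src <- source$items[[item]]
  if (is.null(src)) stop("item ", item, " not present in mind ", source$id)
  if (new_id %in% names(target$items)) stop("duplicate item id: ", new_id)
  it <- new_item(new_id, label %||% src$label,
                 origin_mind = src$origin_mind, provenance = "social",
                 source_mind = source$id, source_item = item)
  target$items[[new_id]] <- it
  target$foodset <- sort(c(target$foodset, new_id))
  target
}

#' Representational redescription: a catalysed cognitive reaction
#'
#' Creates a reaction whose reactants are existing MRs, catalysed by an
#' existing MR, and whose product is a new foodset-derived item (a member of
#' the mind's not-F set). Unary reactions (a single reactant reinterpreted)
#' are supported.
#'
#' @param m a [mind()].
#' @param reactants non-empty vector of item ids present in `m`.
#' @param catalyst item id present in `m` (an external stimulus must first be
#'   brought into the mind via [transmit()] or [add_foodset_item()]).
#' @param product id for the new derived item.
#' @param label label for the product.
#' @param reaction_id id for the reaction (default `r<k>` for the next k).
#' @return the updated mind; the new reaction id is in
#'   `attr(, "reaction_id")` and the product id in `attr(, "product_id")`.
#' @export
redescribe <- function(m, reactants, catalyst, product, label = product,
                       reaction_id = NULL) {
  miss <- setdiff(c(reactants, catalyst), names(m$items))
  if (length(miss))
    stop("missing reactant/catalyst item(s) in mind ", m$id, ": ",
         paste(miss, collapse = ", "))
  if (product %in% names(m$items)) stop("duplicate item id: ", product)
  rid <- reaction_id %||% paste0("r", length(m$reactions) + 1L)
  if (rid %in% names(m$reactions)) stop("duplicate reaction id: ", rid)
  r <- reaction(rid, reactants, product)
  m$reactions[[rid]] <- r
  m$reactions <- m$reactions[order(names(m$reactions))]
  m$catalysis <- unique(rbind(m$catalysis,
                              data.frame(catalyst = catalyst, reaction = rid,
                                         stringsAsFactors = FALSE)))
  it <- new_item(product, label, origin_mind = m$id, provenance = "derived",
                 reaction = rid)
  m$items[[product]] <- it
  m$derived <- sort(c(m$derived, product))
  attr(m, "reaction_id") <- rid
  attr(m, "product_id") <- product
  m
}

raf_label <- function(rids) paste(sort(rids), collapse = "+")

#' Refresh a mind's tracked RAFs and impact weights
#'
#' Recomputes the irreducible RAFs of [mind_to_system()] and reconciles them
#' with the tracked set: a RAF with the same reaction set keeps its impact
#' weight, newly appeared irrRAFs start at weight 1, and vanished ones are
#' dropped. Labels are the sorted reaction ids joined by `+`.
#'
#' @param m a [mind()].
#' @param limit exhaustive enumeration cap passed to [irr_rafs()].
#' @return the updated mind.
#' @export
refresh_rafs <- function(m, limit = 14L) {
  irr <- irr_rafs(mind_to_system(m), "exhaustive", limit = limit)
  labels <- vapply(irr, raf_label, "")
  impact <- stats::setNames(rep(1, length(labels)), labels)
  keep <- intersect(labels, names(m$impact))
  impact[keep] <- m$impact[keep]
  m$rafs <- stats::setNames(irr, labels)
  m$impact <- impact
  m$inhibitions <- m$inhibitions[m$inhibitions$raf %in% labels, , drop = FALSE]
  m
}

#' Declare an inhibitory item against a tracked RAF
#'
#' Records that `item` is inconsistent with the belief cluster labelled
#' `raf`, and multiplicatively weakens that RAF's impact weight by
#' `1 - beta`. Inhibition never enters RAF detection itself — it weakens a
#' RAF's influence rather than blocking its reactions — and the weight stays
#' strictly positive.
#'
#' @param m a [mind()].
#' @param item id of an item present in `m`.
#' @param raf label of a tracked RAF (see [refresh_rafs()]).
#' @return the updated mind.
#' @export
declare_inhibition <- function(m, item, raf) {
  if (!item %in% names(m$items)) stop("unknown item: ", item)
  if (!raf %in% names(m$impact)) stop("unknown RAF label: ", raf)
  m$inhibitions <- unique(rbind(m$inhibitions,
                                data.frame(item = item, raf = raf,
                                           stringsAsFactors = FALSE)))
  m$impact[[raf]] <- m$impact[[raf]] * (1 - m$beta)
  m
}

#' Record a supporting event for a tracked RAF
#'
#' A supporting (confirming, reinforcing) event multiplies the RAF's impact
#' weight by `1 + alpha`.
#'
#' @inheritParams declare_inhibition
#' @return the updated mind.
#' @export
support_raf <- function(m, raf) {
  if (!raf %in% names(m$impact)) stop("unknown RAF label: ", raf)
  m$impact[[raf]] <- m$impact[[raf]] * (1 + m$alpha)
  m
}

#' Derivation DAG of a mental representation
#'
#' Traces a derived item back through its producing reactions to the foodset
#' items it is grounded in. Recursion follows reactants; catalysts appear as
#' annotated edges but are not expanded. For a foodset item the DAG is the
#' trivial single node.
#'
#' @param m a [mind()].
#' @param item item id.
#' @return a list with `item`, `nodes` (data frame: id, provenance) and
#'   `edges` (data frame: from, to, reaction, role in
#'   reactant/catalyst), plus `grounded`: TRUE iff every source of the
#'   reactant lineage lies in the mind's foodset.
#' @export
provenance_chain <- function(m, item) {
  if (!item %in% names(m$items)) stop("unknown item: ", item)
  lineage <- character()   # nodes reached by reactant recursion (incl. item)
  cat_nodes <- character() # catalysts, annotated but not expanded
  edges <- data.frame(from = character(), to = character(),
                      reaction = character(), role = character(),
                      stringsAsFactors = FALSE)
  visit <- function(id) {
    if (id %in% lineage) return(invisible())
    lineage <<- c(lineage, id)
    it <- m$items[[id]]
    if (it$provenance != "derived") return(invisible())
    r <- m$reactions[[it$reaction]]
    for (a in unique(r$reactants)) {
      edges[nrow(edges) + 1L, ] <<- list(a, id, r$id, "reactant")
      visit(a)
    }
    for (cc in m$catalysis$catalyst[m$catalysis$reaction == r$id]) {
      edges[nrow(edges) + 1L, ] <<- list(cc, id, r$id, "catalyst")
      cat_nodes <<- c(cat_nodes, cc)
    }
  }
  visit(item)
  nodes <- union(lineage, cat_nodes)
  prov <- vapply(nodes, function(i) m$items[[i]]$provenance, "")
  sources <- lineage[vapply(lineage, function(i)
    m$items[[i]]$provenance != "derived", TRUE)]
  list(item = item,
       nodes = data.frame(id = nodes, provenance = unname(prov),
                          stringsAsFactors = FALSE),
       edges = edges,
       sources = sources,
       grounded = all(sources %in% m$foodset) &&
         all(vapply(lineage, function(i)
           m$items[[i]]$provenance != "derived" || i %in% edges$to, TRUE)))
}

#' Project a mind onto its catalytic reaction system
#'
#' X = the mind's items, R = its reactions, C = its catalysis edges, F = its
#' foodset. Inhibition edges and impact weights are annotations of the
#' cognitive layer and are dropped.
#'
#' @param m a [mind()].
#' @return a [reaction_system()].
#' @export
mind_to_system <- function(m) {
  reaction_system(types = names(m$items), reactions = unname(m$reactions),
                  catalysis = m$catalysis, foodset = m$foodset)
}

#' DOT export of a mind
#'
#' Foodset items are drawn as double circles, derived items as plain
#' ellipses, reactions as boxes; tracked RAFs become dashed clusters.
#'
#' @param m a [mind()].
#' @return DOT source as a string.
#' @export
mind_to_dot <- function(m) {
  to_dot(mind_to_system(m), highlight = unname(m$rafs), name = m$id)
}

# ---- dyads and session logs -------------------------------------------------

#' Create a dyad with an event log
#'
#' A dyad couples two minds (by convention a client and a therapist) with an
#' ordered session log. The constructor snapshots the initial minds; events
#' are appended and applied with [dyad_event()], and [replay()] reconstructs
#' the final state deterministically from the snapshot and the log.
#'
#' @param client,therapist [mind()] objects.
#' @return an object of class `raf_dyad`.
#' @export
dyad <- function(client, therapist) {
  d <- structure(list(client = client, therapist = therapist, log = list()),
                 class = "raf_dyad")
  d$initial <- list(client = client, therapist = therapist)
  d
}

#' @export
print.raf_dyad <- function(x, ...) {
  cat("<raf_dyad> ", x$client$id, " / ", x$therapist$id, ", ",
      length(x$log), " logged events\n", sep = "")
  invisible(x)
}

get_mind <- function(d, id) {
  if (d$client$id == id) return(d$client)
  if (d$therapist$id == id) return(d$therapist)
  stop("no mind with id ", id, " in this dyad")
}

set_mind <- function(d, m) {
  if (d$client$id == m$id) d$client <- m
  else if (d$therapist$id == m$id) d$therapist <- m
  else stop("no mind with id ", m$id, " in this dyad")
  d
}

apply_event <- function(d, ev) {
  m <- get_mind(d, ev$actor)
  p <- ev$payload
  m2 <- switch(ev$kind,
    add = add_foodset_item(m, p$id, p$label %||% p$id,
                           p$provenance %||% "individual"),
    transmit = {
      target <- get_mind(d, p$to)
      target <- transmit(m, p$item, target, new_id = p$new_id %||% p$item,
                         label = p$label)
      d <- set_mind(d, target)
      m
    },
    react = {
      mm <- redescribe(m, p$reactants, p$catalyst, p$product,
                       label = p$label %||% p$product,
                       reaction_id = p$reaction_id)
      refresh_rafs(mm)
    },
    inhibit = declare_inhibition(m, p$item, p$raf),
    reweight = support_raf(m, p$raf),
    stop("unknown event kind: ", ev$kind)
  )
  set_mind(d, m2)
}

#' Append and apply a session event
#'
#' Event kinds: `"add"` (direct-experience foodset addition; payload `id`,
#' `label`, `provenance`), `"transmit"` (payload `item`, `to`, `new_id`,
#' `label`; the actor is the sending mind), `"react"` (payload `reactants`,
#' `catalyst`, `product`, `label`, `reaction_id`; tracked RAFs are refreshed
#' afterwards), `"inhibit"` (payload `item`, `raf`) and `"reweight"`
#' (supporting event; payload `raf`).
#'
#' @param d a [dyad()].
#' @param kind event kind.
#' @param actor acting mind id.
#' @param payload named list, see above.
#' @param step free-form step label (e.g. `"1a"`).
#' @return the updated dyad.
#' @export
dyad_event <- function(d, kind, actor, payload = list(), step = NA_character_) {
  ev <- list(kind = kind, actor = actor, payload = payload, step = step)
  d <- apply_event(d, ev)
  d$log[[length(d$log) + 1L]] <- ev
  d
}

#' Replay a dyad's session log from its initial snapshot
#'
#' @param d a [dyad()].
#' @param trace if TRUE, attach attribute `"trace"`: a list of per-event
#'   snapshots `(step, kind, actor, impact)` with the acting mind's impact
#'   map after the event.
#' @return a dyad reconstructed by re-applying every logged event; replay is
#'   deterministic and idempotent.
#' @export
replay <- function(d, trace = FALSE) {
  fresh <- dyad(d$initial$client, d$initial$therapist)
  snapshots <- list()
  for (ev in d$log) {
    fresh <- apply_event(fresh, ev)
    fresh$log[[length(fresh$log) + 1L]] <- ev
    if (trace) {
      m <- get_mind(fresh, ev$actor)
      snapshots[[length(snapshots) + 1L]] <-
        list(step = ev$step, kind = ev$kind, actor = ev$actor,
             impact = m$impact)
    }
  }
  if (trace) attr(fresh, "trace") <- snapshots
  fresh
}

#' Impact-weight trajectory of one tracked RAF
#'
#' @param d a [dyad()].
#' @param mind_id whose impact map to follow.
#' @param raf RAF label.
#' @return data frame with columns `step`, `kind` and `weight` (NA before the
#'   RAF is first tracked), one row per logged event of that mind.
#' @export
impact_trajectory <- function(d, mind_id, raf) {
  tr <- attr(replay(d, trace = TRUE), "trace")
  tr <- Filter(function(s) s$actor == mind_id, tr)
  data.frame(
    step = vapply(tr, function(s) s$step %||% NA_character_, ""),
    kind = vapply(tr, `[[`, "", "kind"),
    weight = vapply(tr, function(s)
      if (raf %in% names(s$impact)) s$impact[[raf]] else NA_real_, 1),
    stringsAsFactors = FALSE
  )
}

#' Serialize a dyad to JSON
#'
#' @param d a [dyad()].
#' @return a JSON string with fields `minds` (initial snapshots) and `log`.
#' @export
dyad_to_json <- function(d) {
  mind_doc <- function(m) list(
    id = m$id, alpha = m$alpha, beta = m$beta,
    items = unname(lapply(m$items, function(it)
      Filter(Negate(is.null), it)))
  )
  as.character(jsonlite::toJSON(list(
    format_version = 1L,
    minds = list(mind_doc(d$initial$client), mind_doc(d$initial$therapist)),
    log = d$log
  ), auto_unbox = TRUE, pretty = TRUE, null = "null"))
}
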