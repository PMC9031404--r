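#' Catalytic reaction systems
#'
#' A catalytic reaction system is the tuple Q = (X, R, C, F): a set `X` of
#' entity types, a set `R` of reactions (each with a reactant multiset and a
#' product multiset over `X`), a catalysis relation `C` between types and
#' reactions, and a distinguished foodset `F` (a subset of `X`) of types
#' assumed to be present from the outset.
#'
#' `reaction_system()` validates and canonicalises its inputs: types, foodset
#' and catalysis edges are sorted and deduplicated, reactions are sorted by id.
#' Reactants and products are multisets (an id may repeat); all RAF logic in
#' this package operates on the underlying sets of distinct ids, multiplicity
#' is preserved only through serialization.
#'
#' @param types character vector of type ids. Ids are case-sensitive tokens
#'   without whitespace or the reserved characters `+ -> [ ] ,`.
#' @param reactions list of reactions created with [reaction()].
#' @param catalysis data frame with columns `catalyst` (a type id) and
#'   `reaction` (a reaction id), or a list of such pairs. Duplicate edges
#'   collapse to one.
#' @param foodset character vector of type ids, a subset of `types`.
#' @return an object of class `raf_system` with elements `types`, `reactions`
#'   (a named list), `catalysis` (a data frame) and `foodset`.
#' @examples
#' q <- reaction_system(
#'   types = c("GC", "PC", "mC", "b1C"),
#'   reactions = list(reaction("r1", c("GC", "PC"), "b1C")),
#'   catalysis = data.frame(catalyst = "mC", reaction = "r1"),
#'   foodset = c("GC", "PC", "mC")
#' )
#' max_raf(q)$subset
#' @export
reaction_system <- function(types = character(), reactions = list(),
                            catalysis = NULL, foodset = character()) {
  types <- sort(unique(as.character(types)))
  check_type_ids(types)
  if (is.null(catalysis)) {
    catalysis <- data.frame(catalyst = character(), reaction = character(),
                            stringsAsFactors = FALSE)
  }
  if (is.list(catalysis) && !is.data.frame(catalysis)) {
    catalysis <- do.call(rbind, lapply(catalysis, function(e) {
      data.frame(catalyst = e[[1]], reaction = e[[2]], stringsAsFactors = FALSE)
    }))
    if (is.null(catalysis)) {
      catalysis <- data.frame(catalyst = character(), reaction = character(),
                              stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(catalysis),
            all(c("catalyst", "reaction") %in% names(catalysis)))
  catalysis <- unique(catalysis[, c("catalyst", "reaction")])
  catalysis <- catalysis[order(catalysis$reaction, catalysis$catalyst), ,
                         drop = FALSE]
  rownames(catalysis) <- NULL

  if (length(reactions) && !all(vapply(reactions, inherits, TRUE, "raf_reaction")))
    stop("`reactions` must be a list of objects created with reaction()")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1])
  names(reactions) <- rids
  reactions <- reactions[order(rids)]

  foodset <- sort(unique(as.character(foodset)))

  q <- structure(list(types = types, reactions = reactions,
                      catalysis = catalysis, foodset = foodset),
                 class = "raf_system")
  validate_system(q)
  q
}

#' Construct a reaction
#'
#' @param id reaction id token.
#' @param reactants character vector of type ids consumed (multiset: an id
#'   may appear more than once); must be non-empty.
#' @param products character vector of type ids produced; must be non-empty.
#' @return an object of class `raf_reaction`.
#' @export
reaction <- function(id, reactants, products) {
  id <- as.character(id)
  reactants <- as.character(reactants)
  products <- as.character(products)
  if (length(id) != 1L || !nzchar(id)) stop("reaction id must be one non-empty token")
  if (!length(reactants)) stop("reaction ", id, ": reactants must be non-empty")
  if (!length(products)) stop("reaction ", id, ": products must be non-empty")
  structure(list(id = id, reactants = sort(reactants), products = sort(products)),
            class = "raf_reaction")
}

reserved_id_re <- "[][+,[:space:]]|->|→"

check_type_ids <- function(ids) {
  bad <- ids[!nzchar(ids) | grepl(reserved_id_re, ids)]
  if (length(bad))
    stop("invalid type id(s): ", paste(sQuote(bad), collapse = ", "),
         " (ids are non-empty tokens without whitespace or '+', '->', '[', ']', ',')")
  invisible(ids)
}

validate_system <- function(q) {
  undeclared <- setdiff(q$foodset, q$types)
  if (length(undeclared))
    stop("foodset refers to undeclared type(s): ", paste(undeclared, collapse = ", "))
  for (r in q$reactions) {
    miss <- setdiff(unique(c(r$reactants, r$products)), q$types)
    if (length(miss))
      stop("reaction ", r$id, " refers to undeclared type(s): ",
           paste(miss, collapse = ", "))
  }
  if (nrow(q$catalysis)) {
    miss_t <- setdiff(q$catalysis$catalyst, q$types)
    if (length(miss_t))
      stop("catalysis refers to undeclared type(s): ", paste(miss_t, collapse = ", "))
    miss_r <- setdiff(q$catalysis$reaction, names(q$reactions))
    if (length(miss_r))
      stop("catalysis refers to unknown reaction(s): ", paste(miss_r, collapse = ", "))
  }
  invisible(q)
}

#' @export
print.raf_system <- function(x, ...) {
  cat("<raf_system> ", length(x$types), " types, ",
      length(x$reactions), " reactions, ",
      nrow(x$catalysis), " catalysis edges, foodset of ",
      length(x$foodset), "\n", sep = "")
  invisible(x)
}

#' @export
format.raf_reaction <- function(x, ...) {
  paste0(x$id, ": ", paste(x$reactants, collapse = " + "), " -> ",
         paste(x$products, collapse = " + "))
}

#' @export
print.raf_reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`==.raf_system` <- function(e1, e2) {
  identical(write_system(e1, "json"), write_system(e2, "json"))
}

#' Parse a catalytic reaction system
#'
#' Two dialects are supported. The JSON dialect is the normative form: a
#' document with fields `format_version` (currently 1), `types`, `foodset`,
#' `reactions` (objects with `id`, `reactants`, `products`) and `catalysis`
#' (objects with `catalyst`, `reaction`). The line-oriented text dialect is
#' convenience sugar:
#'
#' ```
#' # comment
#' F: GC, PC, mC
#' X: b1C            # optional explicit type declarations
#' r1: GC + PC -> b1C
#' cat: mC r1
#' ```
#'
#' `F:` lines (one or more, unioned) declare foodset types; `X:` lines declare
#' additional types; `<rid>: a + b -> c` lines declare reactions; `cat:` lines
#' declare catalysis edges. Unless `strict = TRUE`, types are auto-declared by
#' their appearance in `F:` lines or reactions; references to types that
#' appear nowhere raise an error, never silently create types (with
#' `strict = TRUE` every type must appear on an `X:` or `F:` line).
#'
#' @param text a single string (or vector of lines for the text dialect).
#' @param dialect `"text"` or `"json"`.
#' @param strict text dialect only: require every referenced type to be
#'   declared on an `X:`/`F:` line.
#' @return a validated [reaction_system()].
#' @seealso [write_system()], [read_system()]
#' @export
parse_system <- function(text, dialect = c("text", "json"), strict = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "json") parse_system_json(text) else parse_system_text(text, strict)
}

#' Read a reaction system from a file
#'
#' @param path file path. The dialect defaults to `"json"` for a `.json`
#'   extension and `"text"` otherwise.
#' @inheritParams parse_system
#' @export
read_system <- function(path, dialect = NULL, strict = FALSE) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "text"
  parse_system(paste(readLines(path, warn = FALSE), collapse = "\n"),
               dialect = dialect, strict = strict)
}

parse_system_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("JSON syntax error: ", conditionMessage(e)))
  if (is.null(doc$format_version) || doc$format_version != 1)
    stop("unsupported or missing format_version (expected 1)")
  reactions <- lapply(doc$reactions, function(r) {
    reaction(r$id, unlist(r$reactants), unlist(r$products))
  })
  catalysis <- if (length(doc$catalysis)) {
    data.frame(catalyst = vapply(doc$catalysis, `[[`, "", "catalyst"),
               reaction = vapply(doc$catalysis, `[[`, "", "reaction"),
               stringsAsFactors = FALSE)
  }
  reaction_system(types = unlist(doc$types) %||% character(),
                  reactions = reactions, catalysis = catalysis,
                  foodset = unlist(doc$foodset) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_ids <- function(s, lineno, sep = ",") {
  ids <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("line ", lineno, ": empty id list")
  ids
}

parse_system_text <- function(text, strict = FALSE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  declared <- character()
  foodset <- character()
  reactions <- list()
  catalysis <- list()
  referenced <- character()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([^:[:space:]]+):(.*)$", line))[[1]]
    if (length(m) != 3L)
      stop("line ", i, ": syntax error, expected '<key>: ...' (got ", sQuote(line), ")")
    key <- m[2]; body <- trimws(m[3])
    if (key == "F") {
      ids <- split_ids(body, i)
      foodset <- union(foodset, ids)
      declared <- union(declared, ids)
    } else if (key == "X") {
      declared <- union(declared, split_ids(body, i))
    } else if (key == "cat") {
      parts <- strsplit(body, "[[:space:]]+")[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) != 2L)
        stop("line ", i, ": 'cat:' expects '<typeid> <reactionid>'")
      catalysis[[length(catalysis) + 1L]] <- parts
      referenced <- union(referenced, parts[1])
    } else {
      arrow <- regexpr("->", body, fixed = TRUE)
      if (arrow < 0) stop("line ", i, ": reaction line missing '->'")
      lhs <- split_ids(substr(body, 1L, arrow - 1L), i, sep = "+")
      rhs <- split_ids(substr(body, arrow + 2L, nchar(body)), i, sep = "+")
      if (!is.null(reactions[[key]])) stop("line ", i, ": duplicate reaction id ", key)
      reactions[[key]] <- reaction(key, lhs, rhs)
      refs <- unique(c(lhs, rhs))
      if (strict) referenced <- union(referenced, refs)
      else declared <- union(declared, refs)
    }
  }
  undeclared <- setdiff(referenced, declared)
  if (length(undeclared))
    stop("reference to undeclared type(s): ", paste(undeclared, collapse = ", "))
  reaction_system(types = declared, reactions = unname(reactions),
                  catalysis = catalysis, foodset = foodset)
}

#' Serialize a reaction system
#'
#' Output is canonical: types, foodset, reactions and catalysis edges are each
#' sorted by id, so the result is independent of construction order and
#' `parse_system(write_system(q)) == q` for every valid system.
#'
#' @param q a [reaction_system()].
#' @param dialect `"text"` or `"json"`.
#' @return a single string.
#' @export
write_system <- function(q, dialect = c("text", "json")) {
  dialect <- match.arg(dialect)
  validate_system(q)
  if (dialect == "json") {
    doc <- list(
      format_version = 1L,
      types = as.list(q$types),
      foodset = as.list(q$foodset),
      reactions = lapply(q$reactions, function(r)
        list(id = r$id, reactants = as.list(r$reactants),
             products = as.list(r$products))),
      catalysis = if (nrow(q$catalysis)) {
        lapply(seq_len(nrow(q$catalysis)), function(i)
          list(catalyst = q$catalysis$catalyst[i],
               reaction = q$catalysis$reaction[i]))
      } else list()
    )
    doc$reactions <- unname(doc$reactions)
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)))
  }
  out <- c("# catalytic reaction system (format_version 1)")
  if (length(q$foodset)) out <- c(out, paste0("F: ", paste(q$foodset, collapse = ", ")))
  extra <- setdiff(q$types, q$foodset)
  if (length(extra)) out <- c(out, paste0("X: ", paste(extra, collapse = ", ")))
  for (r in q$reactions) out <- c(out, format(r))
  if (nrow(q$catalysis))
    out <- c(out, paste0("cat: ", q$catalysis$catalyst, " ", q$catalysis$reaction))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Restrict a system to a reaction subset
#'
#' Keeps all types and the foodset, drops reactions outside `reactions` and
#' any catalysis edge pointing at a dropped reaction.
#'
#' @param q a [reaction_system()].
#' @param reactions reaction ids to keep.
#' @return a [reaction_system()].
#' @export
subsystem <- function(q, reactions) {
  idx <- match(reactions, names(q$reactions))
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(reactions[is.na(idx)], collapse = ", "))
  reaction_system(types = q$types,
                  reactions = unname(q$reactions[idx]),
                  catalysis = q$catalysis[q$catalysis$reaction %in% reactions, ,
                                          drop = FALSE],
                  foodset = q$foodset)
}

#' Export a reaction system as a DOT graph
#'
#' Renders the bipartite structure of a catalytic reaction system in the DOT
#' graph description language: type nodes as ellipses (foodset types doubled),
#' reaction nodes as boxes, solid edges for reactant/product participation and
#' dashed edges for catalysis. Reactions named in `highlight` are grouped into
#' a dashed cluster — the visual analogue of drawing an oval around a RAF.
#'
#' @param q a [reaction_system()].
#' @param highlight optional reaction-id vector, or a list of such vectors
#'   (one cluster each).
#' @param name graph name.
#' @return DOT source as a single string.
#' @export
to_dot <- function(q, highlight = NULL, name = "raf") {
  validate_system(q)
  if (!is.null(highlight) && !is.list(highlight)) highlight <- list(highlight)
  highlight <- highlight[vapply(highlight, length, 1L) > 0L]
  for (h in highlight) {
    bad <- setdiff(h, names(q$reactions))
    if (length(bad))
      stop("highlight contains unknown reaction id(s): ", paste(bad, collapse = ", "))
  }
  esc <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c(paste0("digraph ", esc(name), " {"),
             "  rankdir=LR;")
  for (t in q$types) {
    shape <- if (t %in% q$foodset) "doublecircle" else "ellipse"
    lines <- c(lines, paste0("  ", esc(t), " [shape=", shape, "];"))
  }
  for (i in seq_along(highlight)) {
    lines <- c(lines, paste0("  subgraph cluster_raf", i, " {"),
               "    style=dashed;",
               paste0("    label=\"RAF ", i, "\";"),
               paste0("    ", esc(highlight[[i]]), " [shape=box];"),
               "  }")
  }
  rest <- setdiff(names(q$reactions), unlist(highlight))
  for (rid in rest) lines <- c(lines, paste0("  ", esc(rid), " [shape=box];"))
  for (r in q$reactions) {
    for (a in unique(r$reactants))
      lines <- c(lines, paste0("  ", esc(a), " -> ", esc(r$id), ";"))
    for (b in unique(r$products))
      lines <- c(lines, paste0("  ", esc(r$id), " -> ", esc(b), ";"))
  }
  if (nrow(q$catalysis))
    lines <- c(lines, paste0("  ", esc(q$catalysis$catalyst), " -> ",
                             esc(q$catalysis$reaction), " [style=dashed];"))
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}
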