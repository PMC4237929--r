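#' The closed predicate vocabulary of the triage engine
#'
#' Decision nodes may test only these named predicates over a card's vital
#' signs; every predicate is boolean with outcomes `"yes"` / `"no"`:
#'
#' * `death_signs_present` — `death_signs != "none"`.
#' * `spurting_haemorrhage` — the bleeding flag itself.
#' * `can_walk` — the walking flag.
#' * `unconscious` — `consciousness == "unconscious"`.
#' * `breathing_disorder_or_apnoea` — `breathing` is `"disorder"` or
#'   `"apnoea"` (the algorithm's single respiration step; no respiratory-rate
#'   counting).
#' * `circulation_abnormal` — radial pulse absent or abnormal skin signs.
#'
#' The vocabulary is closed so that an algorithm document using an unknown
#' test fails validation rather than silently misclassifying.
#'
#' @return named list mapping predicate name to the card columns it reads.
#' @export
predicate_vocabulary <- function() {
  list(
    death_signs_present = "death_signs",
    spurting_haemorrhage = "spurting_haemorrhage",
    can_walk = "can_walk",
    unconscious = "consciousness",
    breathing_disorder_or_apnoea = "breathing",
    circulation_abnormal = c("radial_pulse_present", "skin_abnormal")
  )
}

eval_predicate <- function(predicate, card, node_id) {
  needed <- predicate_vocabulary()[[predicate]]
  for (field in needed) {
    if (is.na(card[[field]])) {
      stop(sprintf(
        "cannot evaluate node %s: vitals field `%s` is missing (NA) on card %s",
        sQuote(node_id), field, sQuote(card[["card_id"]])
      ), call. = FALSE)
    }
  }
  yes <- switch(predicate,
    death_signs_present = card[["death_signs"]] != "none",
    spurting_haemorrhage = card[["spurting_haemorrhage"]],
    can_walk = card[["can_walk"]],
    unconscious = card[["consciousness"]] == "unconscious",
    breathing_disorder_or_apnoea =
      card[["breathing"]] %in% c("disorder", "apnoea"),
    circulation_abnormal =
      !card[["radial_pulse_present"]] || card[["skin_abnormal"]]
  )
  if (yes) "yes" else "no"
}

known_actions <- function() c("indicate_airway_lsi", "indicate_bleeding_lsi")

#' Load and validate a triage-algorithm document
#'
#' A triage algorithm is a rooted decision tree stored as a JSON document
#' with fields `name`, `root` and `nodes`. Each node is one of
#'
#' * a decision node: `predicate` from the closed vocabulary
#'   ([predicate_vocabulary()]) and a `branches` map with an explicit target
#'   for every outcome (`"yes"` and `"no"`),
#' * an action node: `actions` (a subset of `indicate_airway_lsi`,
#'   `indicate_bleeding_lsi`) and a single `next` target — with a
#'   `predicate` the actions fire only on a `"yes"` outcome and flow
#'   continues to `next` either way (the flowchart side-box, e.g. "spurting
#'   haemorrhage: indicate bleeding control, then continue"), or
#' * a leaf: `assign` naming the triage category (optionally with `actions`).
#'
#' Validation collects every violation before failing: unknown predicates or
#' actions, dangling branch targets, missing branches, leaves without an
#' assign action, nodes with more than one parent, cycles, and nodes
#' unreachable from the root.
#'
#' @param spec_document path to a JSON file, a JSON string, or an equivalent
#'   nested list.
#' @return an object of class `triage_algorithm`.
#' @seealso [asav_algorithm()], [start_style_algorithm()], [classify_cards()]
#' @examples
#' alg <- asav_algorithm()
#' alg
#' @export
load_algorithm <- function(spec_document) {
  doc <- if (is.list(spec_document)) {
    spec_document
  } else {
    jsonlite::fromJSON(spec_document, simplifyVector = FALSE)
  }
  for (field in c("name", "root", "nodes")) {
    if (is.null(doc[[field]])) {
      stop("algorithm document lacks required field `", field, "`",
           call. = FALSE)
    }
  }

  nodes <- doc$nodes
  ids <- purrr::map_chr(nodes, "id")
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))

  if (anyDuplicated(ids)) {
    note("duplicate node id(s): %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!doc$root %in% ids) note("root %s is not a node id", sQuote(doc$root))

  node_by_id <- stats::setNames(nodes, ids)
  children <- list()
  for (node in nodes) {
    id <- node$id
    has_predicate <- !is.null(node$predicate)
    has_next <- !is.null(node[["next"]])
    is_leaf <- !is.null(node$assign)
    if (!has_predicate && !has_next && !is_leaf) {
      note("node %s is a leaf without an assign-category action", sQuote(id))
      next
    }
    if (has_predicate && !node$predicate %in% names(predicate_vocabulary())) {
      note("node %s uses unknown predicate %s", sQuote(id),
           sQuote(node$predicate))
    }
    if (has_predicate && !has_next && !is_leaf) {
      # pure decision node: an explicit branch per outcome
      missing_branches <- setdiff(c("yes", "no"), names(node$branches))
      if (length(missing_branches) > 0) {
        note("node %s lacks a branch for outcome(s): %s", sQuote(id),
             paste(missing_branches, collapse = ", "))
      }
      children[[id]] <- unlist(node$branches, use.names = FALSE)
    }
    if (has_next) {
      if (is.null(node$actions)) {
        note("node %s has `next` but no actions", sQuote(id))
      }
      children[[id]] <- node[["next"]]
    }
    if (is_leaf) {
      if (!node$assign %in% triage_categories()) {
        note("node %s assigns unknown category %s", sQuote(id),
             sQuote(node$assign))
      }
    }
    bad_actions <- setdiff(unlist(node$actions), known_actions())
    if (length(bad_actions) > 0) {
      note("node %s carries unknown action(s): %s", sQuote(id),
           paste(bad_actions, collapse = ", "))
    }
  }

  all_targets <- unlist(children, use.names = FALSE)
  dangling <- setdiff(all_targets, ids)
  if (length(dangling) > 0) {
    note("dangling branch target(s): %s", paste(dangling, collapse = ", "))
  }
  in_tree_targets <- all_targets[all_targets %in% ids]
  multi_parent <- unique(in_tree_targets[duplicated(in_tree_targets)])
  if (length(multi_parent) > 0) {
    note("node(s) with more than one parent: %s",
         paste(multi_parent, collapse = ", "))
  }
  if (!is.null(doc$root) && doc$root %in% in_tree_targets) {
    note("root %s has a parent (cycle through the root)", sQuote(doc$root))
  }

  # reachability / cycle detection by depth-first walk from the root
  if (doc$root %in% ids) {
    seen <- character()
    stack <- doc$root
    cycle_found <- FALSE
    while (length(stack) > 0) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (cur %in% seen) {
        cycle_found <- TRUE
        next
      }
      seen <- c(seen, cur)
      kids <- children[[cur]]
      stack <- c(kids[kids %in% ids], stack)
    }
    if (cycle_found) note("the node graph contains a cycle")
    unreachable <- setdiff(ids, seen)
    if (length(unreachable) > 0) {
      note("node(s) unreachable from the root: %s",
           paste(unreachable, collapse = ", "))
    }
  }

  if (length(problems) > 0) {
    stop("invalid algorithm document:\n",
         paste("  -", problems, collapse = "\n"), call. = FALSE)
  }

  structure(
    list(name = doc$name, root = doc$root, nodes = node_by_id),
    class = "triage_algorithm"
  )
}

#' @export
print.triage_algorithm <- function(x, ...) {
  n_leaf <- sum(purrr::map_lgl(x$nodes, ~ !is.null(.x$assign)))
  cat("<triage_algorithm> ", x$name, "\n", sep = "")
  cat("  ", length(x$nodes), " nodes (", n_leaf, " leaves), root: ",
      x$root, "\n", sep = "")
  invisible(x)
}

#' Packaged triage algorithms
#'
#' `asav_algorithm()` returns the package's default primary-triage tree, a
#' reconstruction of the Amberg-Schwandorf algorithm (ASAV) from its
#' published textual description: (1) definite signs of death (decapitation,
#' destruction of the torso) assign black — non-physician providers may not
#' otherwise pronounce death; (2) spurting haemorrhage indicates bleeding
#' control and triage continues; (3) walking patients are green; (4)
#' unconscious patients get an airway-opening indication and are red; (5) any
#' breathing disorder or apnoea is red (a single respiration step, no
#' respiratory-rate counting); (6) abnormal circulation (absent radial pulse
#' or abnormal skin signs) is red; (7) otherwise yellow. Because the engine
#' is data-driven, an exact transcription of the published flowchart can be
#' loaded with [load_algorithm()] to replace this reconstruction.
#'
#' `start_style_algorithm()` returns a synthetic START/mSTaRT-style
#' comparator that assesses walking ability first; it keeps the
#' black-only-on-definite-death rule because the closed predicate vocabulary
#' carries no standalone apnoea test.
#'
#' @return a `triage_algorithm` object.
#' @export
asav_algorithm <- function() {
  load_algorithm(system.file("extdata", "asav.json", package = "asavtriage",
                             mustWork = TRUE))
}

#' @rdname asav_algorithm
#' @export
start_style_algorithm <- function() {
  load_algorithm(system.file("extdata", "start_style.json",
                             package = "asavtriage", mustWork = TRUE))
}

classify_one <- function(card, algorithm) {
  node_id <- algorithm$root
  path <- character()
  airway <- FALSE
  bleeding <- FALSE
  assigned <- NA_character_
  repeat {
    node <- algorithm$nodes[[node_id]]
    path <- c(path, node_id)
    outcome <- if (!is.null(node$predicate)) {
      eval_predicate(node$predicate, card, node_id)
    }
    acts <- unlist(node$actions)
    # on a conditional-action node the actions fire only on a "yes" outcome
    if (is.null(outcome) || is.null(node[["next"]]) || outcome == "yes") {
      if ("indicate_airway_lsi" %in% acts) airway <- TRUE
      if ("indicate_bleeding_lsi" %in% acts) bleeding <- TRUE
    }
    if (!is.null(node$assign)) {
      assigned <- node$assign
      break
    }
    node_id <- if (!is.null(node[["next"]])) {
      node[["next"]]
    } else {
      node$branches[[outcome]]
    }
  }
  list(assigned = assigned, airway_lsi = airway, bleeding_lsi = bleeding,
       path = paste(path, collapse = "|"))
}

#' Classify casualty cards with a triage algorithm
#'
#' Deterministically traverses the decision tree for each card, recording
#' every node visited. The assigned category is the leaf's assign action;
#' the lifesaving-intervention flags are the union of indicate actions
#' encountered along the path.
#'
#' @param cards a cards tibble ([new_cards()], [generate_cards()]).
#' @param algorithm a `triage_algorithm`; defaults to the packaged ASAV
#'   reconstruction.
#' @return tibble with one row per card: `card_id`, `assigned`,
#'   `airway_lsi`, `bleeding_lsi` and `path` (`"|"`-joined node ids from the
#'   root to the leaf).
#' @examples
#' cards <- generate_cards(6, seed = 1)
#' classify_cards(cards)
#' @export
classify_cards <- function(cards, algorithm = asav_algorithm()) {
  if (!inherits(algorithm, "triage_algorithm")) {
    stop("`algorithm` must be a triage_algorithm (see load_algorithm())",
         call. = FALSE)
  }
  decisions <- purrr::map(seq_len(nrow(cards)),
                          ~ classify_one(cards[.x, ], algorithm))
  tibble::tibble(
    card_id = cards$card_id,
    assigned = purrr::map_chr(decisions, "assigned"),
    airway_lsi = purrr::map_lgl(decisions, "airway_lsi"),
    bleeding_lsi = purrr::map_lgl(decisions, "bleeding_lsi"),
    path = purrr::map_chr(decisions, "path")
  )
}
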