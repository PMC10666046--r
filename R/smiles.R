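# Molecular graph layer. SMILES parsing and canonicalization are delegated
# to ChemmineR/OpenBabel; the circular-substructure tokenizer and the
# ring-linker fragmenter operate on the parsed graph.

# Parse one or more SMILES into graphs (elements + bond table). Errors name
# the offending input.
parse_smiles_graphs <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ids <- ids %||% sprintf("M%05d", seq_along(smiles))
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids))),
    error = function(e) NULL)
  if (is.null(sdfs) || length(sdfs) != length(smiles)) {
    # locate the failure for a precise error message
    for (i in seq_along(smiles)) {
      ok <- tryCatch({
        suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles[i], ids[i])))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) abort(sprintf("Unparseable SMILES '%s' (id %s).",
                             smiles[i], ids[i]))
    }
    abort("SMILES parsing failed.")
  }
  lapply(seq_along(smiles), function(i) {
    # bare single atoms produce SDF blocks OpenBabel leaves degenerate
    if (grepl("^(Cl|Br|[BCNOSPFI])$", smiles[i])) {
      return(list(smiles = smiles[i], id = ids[i], elements = smiles[i],
                  bonds = data.frame(i = integer(), j = integer(),
                                     order = integer())))
    }
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    if (!is.matrix(bb) && length(bb) > 0L) bb <- matrix(bb, nrow = 1L)
    bonds <- if (NROW(bb) == 0L) {
      data.frame(i = integer(), j = integer(), order = integer())
    } else {
      data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                 order = as.integer(bb[, 3L]))
    }
    list(smiles = smiles[i], id = ids[i], elements = elements, bonds = bonds)
  })
}

# OpenBabel canonical form, used to deduplicate fragments. Falls back to
# the input string for fragments OpenBabel cannot round-trip (single atoms
# produce bond-less SDF blocks it rejects).
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(s, "x")))
      out <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
      if (length(out) == 1L && nzchar(out)) out else s
    }, error = function(e) s, warning = function(w) s)
  }, character(1), USE.NAMES = FALSE)
}

# Morgan-style invariant strings per atom for radii 0..radius.
atom_environment_tokens <- function(graph, radius) {
  n <- length(graph$elements)
  deg <- integer(n)
  bsum <- integer(n)
  nbrs <- vector("list", n)
  b <- graph$bonds
  for (r in seq_len(NROW(b))) {
    i <- b$i[r]; j <- b$j[r]; o <- b$order[r]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
  }
  inv <- vector("list", radius + 1L)
  inv[[1L]] <- sprintf("%s|d%d|b%d", graph$elements, deg, bsum)
  for (r in seq_len(radius)) {
    prev <- inv[[r]]
    inv[[r + 1L]] <- vapply(seq_len(n), function(v) {
      nb <- nbrs[[v]]
      parts <- if (NROW(nb) == 0L) character(0) else
        sort(sprintf("%d~%s", nb[, 2L], prev[nb[, 1L]]))
      paste0(prev[v], "[", paste(parts, collapse = ","), "]")
    }, character(1))
  }
  inv
}

#' Tokenize a compound into circular-substructure identifiers
#'
#' Emits, for each atom in parse order and each radius 0..`radius`, a
#' stable identifier of the atom's circular environment (element, degree
#' and bond-order sum at radius 0; recursively including sorted neighbor
#' environments at higher radii). This is the molecular analogue of a
#' k-mer sentence: identical substructures produce identical tokens in any
#' molecule.
#'
#' @param smiles a single SMILES string.
#' @param radius maximum environment radius (default 1).
#' @return Character vector of `(n_atoms * (radius + 1))` identifiers,
#'   atom-major (`atom1 r0, atom1 r1, atom2 r0, ...`).
#' @export
compound_sentence <- function(smiles, radius = 1L) {
  radius <- check_count(radius, "radius", min = 0L)
  graph <- parse_smiles_graphs(smiles)[[1L]]
  inv <- atom_environment_tokens(graph, radius)
  n <- length(graph$elements)
  out <- character(0)
  for (a in seq_len(n)) {
    for (r in seq_len(radius + 1L)) {
      out <- c(out, sprintf("r%d:%s", r - 1L, inv[[r]][a]))
    }
  }
  out
}

#' Decompose a molecule into ring-system fragments
#'
#' Cuts every acyclic single bond whose removal separates two components
#' that each contain at least one ring atom (ring-ring linker bonds), then
#' returns the canonicalized, deduplicated fragment SMILES. A molecule with
#' no breakable bond is returned unchanged, so the operation is idempotent
#' on its own fragments.
#'
#' @param smiles a single SMILES string.
#' @param rule_set currently `"ring_linker"` (the versioned default).
#' @return Character vector of fragment SMILES.
#' @export
decompose_molecule <- function(smiles, rule_set = "ring_linker") {
  if (!identical(rule_set, "ring_linker")) {
    abort(sprintf("Unknown rule set '%s'.", rule_set))
  }
  graph <- parse_smiles_graphs(smiles)[[1L]]
  b <- graph$bonds
  n <- length(graph$elements)
  if (NROW(b) == 0L || n < 2L) return(smiles)
  g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bridge_eids <- igraph::bridges(g)
  ring_atom <- rep(FALSE, n)
  if (length(bridge_eids) < NROW(b)) {
    non_bridge <- setdiff(seq_len(NROW(b)), as.integer(bridge_eids))
    ring_atom[unique(c(b$i[non_bridge], b$j[non_bridge]))] <- TRUE
  }
  if (!any(ring_atom)) return(smiles)

  cut <- integer(0)
  for (eid in as.integer(bridge_eids)) {
    if (b$order[eid] != 1L) next
    # linker attachment: one endpoint must belong to a ring system
    if (!ring_atom[b$i[eid]] && !ring_atom[b$j[eid]]) next
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    side_u <- comp == comp[b$i[eid]]
    if (any(ring_atom & side_u) && any(ring_atom & !side_u)) {
      cut <- c(cut, eid)
    }
  }
  if (length(cut) == 0L) return(smiles)

  gcut <- igraph::delete_edges(g, cut)
  comp <- igraph::components(gcut)$membership
  frags <- vapply(sort(unique(comp)), function(cid) {
    verts <- which(comp == cid)
    keep <- b$i %in% verts & b$j %in% verts &
      !seq_len(NROW(b)) %in% cut
    sub <- b[keep, , drop = FALSE]
    remap <- match(seq_len(n), verts)
    sub$i <- remap[sub$i]
    sub$j <- remap[sub$j]
    graph_to_smiles(graph$elements[verts], sub)
  }, character(1))
  unique(canonical_smiles(frags))
}
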