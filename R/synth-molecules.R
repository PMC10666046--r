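# Generators for protein sequences and SMILES compound libraries.
#
# Each record carries a hidden latent (attribute "latents") that tilts its
# observable composition; interaction and sensitivity generators label pairs
# through the latents only.

VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L, I = 1L)

softmax_tilt <- function(W, z, scale) {
  p <- exp(as.numeric(W %*% z) * scale)
  p / sum(p)
}

#' Generate synthetic protein sequences
#'
#' Sequences over the 20-letter amino-acid alphabet with lengths uniform in
#' `length_range`. Residue frequencies are tilted by a hidden per-protein
#' latent vector (returned as the `latents` attribute) so that sequence
#' composition carries the latent used by [generate_interaction_world()].
#'
#' @param n number of proteins.
#' @param length_range integer `c(min, max)`; `min >= 3` so every sequence
#'   yields at least one amino-acid triplet.
#' @param seed integer seed.
#' @param tilt strength of the latent tilt on residue frequencies
#'   (0 = uniform composition, no recoverable latent).
#' @return Tibble with columns `id`, `sequence`; attribute `latents`
#'   (n x 3 matrix, rownames = ids).
#' @export
generate_proteins <- function(n, length_range = c(50L, 300L), seed, tilt = 0.85) {
  n <- check_count(n, "n")
  if (length(length_range) != 2L || length_range[1] < 3L ||
      length_range[2] < length_range[1]) {
    abort("`length_range` must be c(min, max) with min >= 3.")
  }
  with_seed(seed, {
    z <- matrix(rnorm(n * LATENT_DIM), n, LATENT_DIM)
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n)
    } else {
      sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    }
    seqs <- vapply(seq_len(n), function(i) {
      p <- softmax_tilt(TILT_AA, z[i, ], tilt)
      paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    ids <- sprintf("PRT%04d", seq_len(n))
    rownames(z) <- ids
    out <- tibble(id = ids, sequence = seqs)
    attr(out, "latents") <- z
    attr(out, "tilt") <- tilt
    out
  })
}

# Random valence-respecting molecular graph: a backbone chain with optional
# disjoint rings, halogen leaves, and occasional double bonds. Elements,
# halogen/ring/double-bond frequencies are all tilted by the latent `z`.
random_compound_graph <- function(z, n_heavy, tilt) {
  p_atom <- softmax_tilt(TILT_ATOM, z, tilt * 0.8)
  elements <- sample(CHAIN_ATOMS, n_heavy, replace = TRUE, prob = p_atom)
  bonds <- data.frame(i = seq_len(n_heavy - 1L), j = seq(2L, n_heavy),
                      order = 1L)
  used <- integer(n_heavy)
  for (b in seq_len(nrow(bonds))) {
    used[bonds$i[b]] <- used[bonds$i[b]] + 1L
    used[bonds$j[b]] <- used[bonds$j[b]] + 1L
  }
  spare <- function(v) VALENCE[[elements[v]]] - used[v]

  # rings over disjoint backbone segments
  max_rings <- min(3L, n_heavy %/% 5L)
  p_ring <- plogis(-0.3 + sum(TILT_RING * z) * tilt * 0.6)
  n_rings <- if (max_rings > 0L) rbinom(1L, max_rings, p_ring) else 0L
  taken <- logical(n_heavy)
  for (r in seq_len(n_rings)) {
    len <- sample(5:6, 1L)
    starts <- which(!taken[seq_len(max(0L, n_heavy - len + 1L))])
    starts <- starts[vapply(starts, function(s) !any(taken[s:(s + len - 1L)]),
                            logical(1))]
    if (length(starts) == 0L) break
    s <- sample(starts, 1L)
    e <- s + len - 1L
    if (spare(s) >= 1L && spare(e) >= 1L) {
      bonds <- rbind(bonds, data.frame(i = s, j = e, order = 1L))
      used[s] <- used[s] + 1L
      used[e] <- used[e] + 1L
      taken[s:e] <- TRUE
    }
  }

  # double bonds on C-C backbone edges with spare valence on both ends
  p_dbl <- plogis(-1.5 + sum(TILT_DOUBLE * z) * tilt * 0.5)
  for (b in seq_len(n_heavy - 1L)) {
    iv <- bonds$i[b]; jv <- bonds$j[b]
    if (elements[iv] == "C" && elements[jv] == "C" &&
        spare(iv) >= 1L && spare(jv) >= 1L && runif(1) < p_dbl) {
      bonds$order[b] <- 2L
      used[iv] <- used[iv] + 1L
      used[jv] <- used[jv] + 1L
    }
  }

  # halogen leaves on atoms with spare valence
  p_hal <- plogis(-0.5 + sum(TILT_HALOGEN * z) * tilt * 0.6)
  n_hal <- rbinom(1L, 3L, p_hal)
  for (h in seq_len(n_hal)) {
    hosts <- which(vapply(seq_along(elements), spare, integer(1)) >= 1L &
                     elements %in% c("C", "N"))
    if (length(hosts) == 0L) break
    v <- if (length(hosts) == 1L) hosts else sample(hosts, 1L)
    elements <- c(elements, sample(HALOGENS, 1L))
    w <- length(elements)
    used <- c(used, 1L)
    used[v] <- used[v] + 1L
    bonds <- rbind(bonds, data.frame(i = v, j = w, order = 1L))
  }
  list(elements = elements, bonds = bonds)
}

# Emit a SMILES string for a connected molecular graph (elements + bond
# list). DFS from atom 1; non-tree edges become ring-closure digits.
graph_to_smiles <- function(elements, bonds) {
  n <- length(elements)
  if (n == 1L) return(elements)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- rbind(adj[[bonds$i[b]]], c(bonds$j[b], bonds$order[b]))
    adj[[bonds$j[b]]] <- rbind(adj[[bonds$j[b]]], c(bonds$i[b], bonds$order[b]))
  }
  bond_sym <- function(o) c("", "=", "#")[o]

  visited <- logical(n)
  parent <- integer(n)
  closures <- vector("list", n) # per vertex: list of c(digit, order)
  tree_children <- vector("list", n)
  closure_seen <- new.env()
  digit <- 0L

  # pass 1: DFS to classify edges
  stack <- 1L
  visited[1L] <- TRUE
  order_visit <- integer(0)
  walk <- function(v) {
    order_visit <<- c(order_visit, v)
    nb <- adj[[v]]
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1L]; o <- nb[r, 2L]
      if (!visited[u]) {
        visited[u] <<- TRUE
        parent[u] <<- v
        tree_children[[v]] <<- rbind(tree_children[[v]], c(u, o))
        walk(u)
      } else if (u != parent[v]) {
        key <- paste(sort(c(u, v)), collapse = "-")
        if (is.null(closure_seen[[key]])) {
          digit <<- digit + 1L
          if (digit > 9L) abort("More than 9 ring closures unsupported.")
          closure_seen[[key]] <- digit
          closures[[v]] <<- rbind(closures[[v]], c(digit, o))
          closures[[u]] <<- rbind(closures[[u]], c(digit, o))
        }
      }
    }
  }
  walk(1L)

  emit <- function(v) {
    s <- elements[v]
    cl <- closures[[v]]
    for (r in seq_len(NROW(cl))) {
      s <- paste0(s, bond_sym(cl[r, 2L]), cl[r, 1L])
    }
    ch <- tree_children[[v]]
    nch <- NROW(ch)
    for (r in seq_len(nch)) {
      sub <- paste0(bond_sym(ch[r, 2L]), emit(ch[r, 1L]))
      s <- if (r < nch) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  emit(1L)
}

#' Generate a synthetic SMILES compound library
#'
#' Valid SMILES are built from valence-respecting random molecular graphs
#' (backbone chain over C/N/O/S, disjoint 5-6 rings, halogen leaves,
#' occasional double bonds) and are unique within a call. Atom, ring,
#' halogen and double-bond frequencies are tilted by a hidden per-compound
#' latent (attribute `latents`).
#'
#' @param n number of compounds (>= 1).
#' @param seed integer seed.
#' @param size_range heavy-atom count range.
#' @param tilt latent tilt strength (0 = no recoverable latent).
#' @return Tibble with columns `id`, `smiles`; attribute `latents`.
#' @export
generate_compounds <- function(n, seed, size_range = c(10L, 40L), tilt = 1.1) {
  n <- check_count(n, "n")
  with_seed(seed, {
    z <- matrix(rnorm(n * LATENT_DIM), n, LATENT_DIM)
    smiles <- character(n)
    seen <- new.env()
    for (i in seq_len(n)) {
      sizes <- seq(size_range[1], size_range[2])
      for (attempt in 1:100) {
        m <- sizes[sample.int(length(sizes), 1L)]
        g <- random_compound_graph(z[i, ], m, tilt)
        s <- graph_to_smiles(g$elements, g$bonds)
        if (is.null(seen[[s]])) {
          seen[[s]] <- TRUE
          smiles[i] <- s
          break
        }
      }
      if (smiles[i] == "") {
        abort("Could not generate a unique SMILES after 100 attempts.")
      }
    }
    ids <- sprintf("CMP%05d", seq_len(n))
    rownames(z) <- ids
    out <- tibble(id = ids, smiles = smiles)
    attr(out, "latents") <- z
    attr(out, "tilt") <- tilt
    out
  })
}
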