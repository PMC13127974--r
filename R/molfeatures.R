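#' Parse SMILES into light-weight molecular graphs
#'
#' Uses OpenBabel (via ChemmineR/ChemmineOB) to parse the strings and
#' generate 2-D depiction coordinates, then strips the result down to the
#' fields the feature code needs: element symbols, coordinates, and a bond
#' table with orders.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of `mol_graph` objects (elements, coords, bonds).
#' @export
mol_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  nm <- sprintf("m%06d", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nm))),
    error = function(e) stop("unparseable SMILES in batch: ",
                             conditionMessage(e)))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid))
    stop("unparseable SMILES: ", paste(smiles[!valid], collapse = ", "))
  lapply(seq_along(smiles), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    elements <- gsub("_.*$", "", rownames(ab))
    n <- length(elements)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
      matrix(numeric(0), 0, 3) else unname(bb[, 1:3, drop = FALSE])
    structure(list(smiles = smiles[i], elements = elements,
                   coords = unname(ab[, 1:2, drop = FALSE]),
                   bonds = bonds, n_atoms = n),
              class = "mol_graph")
  })
}

# Deterministic integer mixing kept inside double precision (mod 2^31).
.mix_hash <- function(h, x) ((h * 33) %% 2147483647 + x) %% 2147483647

.elem_code <- c(C = 6, N = 7, O = 8, S = 16, F = 9, Cl = 17, Br = 35,
                P = 15, I = 53, B = 5, H = 1)

# Circular (Morgan-style) substructure identifiers per atom and radius.
.circular_ids <- function(g, radius) {
  n <- g$n_atoms
  nb <- vector("list", n); bo <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      nb[[a]] <- c(nb[[a]], b); bo[[a]] <- c(bo[[a]], o)
      nb[[b]] <- c(nb[[b]], a); bo[[b]] <- c(bo[[b]], o)
    }
  }
  deg <- lengths(nb)
  bosum <- vapply(bo, function(x) sum(x %||% 0), numeric(1))
  code <- .elem_code[g$elements]; code[is.na(code)] <- 0
  ids <- .mix_hash(.mix_hash(.mix_hash(1469, code), deg), bosum)
  out <- list(`0` = ids)
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      if (!deg[i]) return(.mix_hash(ids[i], r))
      env <- sort(bo[[i]] * 2147483647 %% 97 + ids[nb[[i]]] * 7 %% 2147483647)
      h <- .mix_hash(ids[i], r)
      for (e in env) h <- .mix_hash(h, e)
      h
    }, numeric(1))
    ids <- new_ids
    out[[as.character(r)]] <- ids
  }
  out
}

#' Circular fingerprint of a molecule
#'
#' Morgan-style hashed fingerprint: iterative neighbourhood hashing of atom
#' environments up to `radius`, folded into `nbits` bits.  Deterministic
#' per SMILES.
#'
#' @param graph a `mol_graph` from [mol_graphs()].
#' @param radius neighbourhood radius (default 2).
#' @param nbits fingerprint length (default 256).
#' @return integer vector of 0/1 of length `nbits`.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, nbits = 256L) {
  ids <- unlist(.circular_ids(graph, radius), use.names = FALSE)
  fp <- integer(nbits)
  fp[(ids %% nbits) + 1L] <- 1L
  fp
}

# 300-d substructure-embedding block: radius-0/1 circular identifiers
# hashed into a fixed-length count vector, log1p-damped.
.substructure_block <- function(graph, dim = 300L) {
  ids <- unlist(.circular_ids(graph, 1L), use.names = FALSE)
  v <- numeric(dim)
  slot <- (ids %% dim) + 1L
  for (s in slot) v[s] <- v[s] + 1
  log1p(v)
}

#' Assemble the 561-dimensional descriptor vector for compounds
#'
#' Concatenates 5 global descriptors (molecular weight, logP estimate,
#' hydrogen-bond donor and acceptor counts, topological polar surface
#' area; computed with OpenBabel), a 256-bit circular fingerprint of
#' radius 2, and a 300-dimensional hashed substructure-count embedding.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix, one row per compound, 561 named columns.
#' @export
descriptor_matrix <- function(smiles) {
  graphs <- mol_graphs(smiles)
  nm <- sprintf("m%06d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nm)))
  pr <- ChemmineR::propOB(sdf)
  glob <- cbind(MW = pr$MW, LogP = pr$logP, HBD = pr$HBD,
                HBA = pr$HBA1, TPSA = pr$TPSA)
  fps <- t(vapply(graphs, morgan_fingerprint, integer(256)))
  m2v <- t(vapply(graphs, .substructure_block, numeric(300)))
  out <- cbind(glob, fps, m2v)
  colnames(out) <- c("MW", "LogP", "HBD", "HBA", "TPSA",
                     sprintf("fp_%03d", seq_len(256)),
                     sprintf("sub_%03d", seq_len(300)))
  out
}

#' Assemble the descriptor vector for a single compound
#' @param smiles one SMILES string.
#' @return named numeric vector of length 561.
#' @export
assemble_descriptor_vector <- function(smiles) {
  stopifnot(length(smiles) == 1)
  descriptor_matrix(smiles)[1, ]
}

.atom_colors <- list(
  N = c(0.10, 0.10, 0.90), O = c(0.90, 0.10, 0.10),
  S = c(0.80, 0.70, 0.10), F = c(0.10, 0.75, 0.10),
  Cl = c(0.10, 0.60, 0.10), Br = c(0.55, 0.25, 0.10))

#' Render a molecule as a fixed-size RGB image
#'
#' Deterministic 2-D depiction on a white background: bonds are drawn as
#' dark line segments (double bonds as parallel pairs) from the OpenBabel
#' layout coordinates, and heteroatoms are marked with small colour-coded
#' squares.  Identical SMILES always produce bitwise-identical pixels.
#'
#' @param smiles one SMILES string.
#' @param size image side length in pixels (default 224).
#' @return `molecular_image`: list with `pixels` (size x size x 3 array of
#'   intensities in \[0, 1\]) and `smiles`.
#' @export
render_molecule_image <- function(smiles, size = 224L) {
  g <- mol_graphs(smiles)[[1]]
  px <- array(1, dim = c(size, size, 3))
  xy <- g$coords
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-6)
  pad <- 0.1 * size
  sc <- (size - 2 * pad) / span
  X <- (xy[, 1] - mean(rngx)) * sc + size / 2
  Y <- (xy[, 2] - mean(rngy)) * sc + size / 2
  put <- function(ix, iy, col, half = 1L) {
    for (dx in -half:half) for (dy in -half:half) {
      xx <- ix + dx; yy <- iy + dy
      ok <- xx >= 1 & xx <= size & yy >= 1 & yy <= size
      if (any(ok)) for (ch in 1:3) px[cbind(yy[ok], xx[ok], ch)] <<- col[ch]
    }
  }
  draw_seg <- function(x0, y0, x1, y1) {
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
    put(round(x0 + t * (x1 - x0)), round(y0 + t * (y1 - y0)), c(0.1, 0.1, 0.1))
  }
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      draw_seg(X[a], Y[a], X[b], Y[b])
      if (o >= 2) {
        nx <- -(Y[b] - Y[a]); ny <- X[b] - X[a]
        nl <- sqrt(nx^2 + ny^2); if (nl < 1e-9) nl <- 1
        off <- 3
        draw_seg(X[a] + off * nx / nl, Y[a] + off * ny / nl,
                 X[b] + off * nx / nl, Y[b] + off * ny / nl)
      }
    }
  }
  for (i in seq_len(g$n_atoms)) {
    col <- .atom_colors[[g$elements[i]]]
    if (!is.null(col)) put(round(X[i]), round(Y[i]), col, half = 3L)
  }
  structure(list(pixels = px, smiles = smiles), class = "molecular_image")
}
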