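# C3-symmetric trimer coordinate handling: construction, PDB I/O, in-silico
# cysteine substitution and inter-chain distance queries.

#' Trimer (or protomer) structure container
#'
#' A light container for the coordinates of a homotrimeric membrane receptor
#' (or a single protomer awaiting symmetrisation). Atoms are stored as a
#' data frame in PDB author numbering; coordinates are in Angstrom.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`. One row per atom, residues in file order.
#' @param symmetric logical; `TRUE` if the three chains are related by a
#'   120-degree rotation about `axis`.
#' @param axis optional list with components `point` and `direction` giving
#'   the C3 axis; required when `symmetric = TRUE`.
#' @return An object of class `trimer_structure` with fields `atoms`,
#'   `symmetric` and `axis`. `n_chains(x)` is 1 (protomer) or 3 (trimer).
#' @details The three chains of a trimer must carry identical residue
#'   numbers and residue names; construction fails otherwise, naming the
#'   first mismatching residue.
#' @export
trimer_structure <- function(atoms, symmetric = FALSE, axis = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    stop("`atoms` must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  atoms <- atoms[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$elety <- as.character(atoms$elety)
  atoms$resid <- as.character(atoms$resid)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1")
  chains <- unique(atoms$chain)
  if (!(length(chains) %in% c(1L, 3L))) {
    stop("not a protomer or trimer: found ", length(chains), " chain(s)")
  }
  if (length(chains) == 3L) .check_chain_agreement(atoms, chains)
  if (symmetric && is.null(axis)) stop("`axis` required when symmetric = TRUE")
  structure(list(atoms = atoms, symmetric = symmetric, axis = axis),
            class = "trimer_structure")
}

.check_chain_agreement <- function(atoms, chains) {
  ref <- atoms[atoms$chain == chains[1], ]
  ref_key <- unique(paste(ref$resno, ref$resid))
  for (ch in chains[-1]) {
    other <- atoms[atoms$chain == ch, ]
    other_key <- unique(paste(other$resno, other$resid))
    bad <- c(setdiff(ref_key, other_key), setdiff(other_key, ref_key))
    if (length(bad)) {
      stop("chains ", chains[1], " and ", ch,
           " have mismatched residue sets; first mismatch: residue ", bad[1])
    }
  }
}

#' @export
print.trimer_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("trimer_structure:", length(ch),
      if (length(ch) == 1) "chain (protomer)," else "chains,",
      length(unique(x$atoms$resno)), "residues,",
      nrow(x$atoms), "atoms;",
      if (isTRUE(x$symmetric)) "C3 symmetric" else "symmetry not flagged", "\n")
  invisible(x)
}

#' Number of chains in a structure
#' @param x a `trimer_structure`.
#' @return Integer, 1 or 3.
#' @export
n_chains <- function(x) length(unique(x$atoms$chain))

#' Read a protomer or trimer from a PDB file
#'
#' Reads standard `ATOM` records. A single-chain file is returned as a
#' protomer (to be completed with [symmetrize_c3()]); a three-chain file
#' with identical residue sets is returned as a trimer. Insertion codes are
#' rejected; alternate locations other than blank or `A` are dropped.
#'
#' @param path path to a PDB file.
#' @return A [trimer_structure()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(ins))) stop("insertion codes are not supported")
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  at <- at[keep, ]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  trimer_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' @param x a `trimer_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain)
  invisible(path)
}

#' Build a C3 trimer from a single protomer
#'
#' Chains B and C are copies of the protomer rotated by +120 and +240
#' degrees about the given axis, as used when modelling a homotrimeric
#' channel under C3 symmetry constraints.
#'
#' @param protomer a single-chain `trimer_structure`.
#' @param axis_point point on the symmetry axis (default origin).
#' @param axis_direction axis direction (default z, the membrane normal).
#' @return A symmetric three-chain `trimer_structure` with chains A, B, C.
#' @export
symmetrize_c3 <- function(protomer, axis_point = c(0, 0, 0),
                          axis_direction = c(0, 0, 1)) {
  if (n_chains(protomer) != 1L) stop("`protomer` must have exactly one chain")
  if (sqrt(sum(axis_direction^2)) < .Machine$double.eps) {
    stop("zero-length axis vector")
  }
  a <- protomer$atoms
  a$chain <- "A"
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- a
  for (k in 1:2) {
    rot <- a
    rot$chain <- c("B", "C")[k]
    rxyz <- rotate_coords(xyz, axis_direction, k * 2 * pi / 3, axis_point)
    rot$x <- rxyz[, 1]; rot$y <- rxyz[, 2]; rot$z <- rxyz[, 3]
    out <- rbind(out, rot)
  }
  trimer_structure(out, symmetric = TRUE,
                   axis = list(point = axis_point,
                               direction = unit_vector(axis_direction)))
}

#' Check the C3 symmetry invariant
#'
#' Rotates chain A by 120 degrees about the stored axis and reports the RMSD
#' to chain B (and by 240 degrees to chain C).
#'
#' @param x a three-chain `trimer_structure` with an `axis`.
#' @param tol RMSD tolerance in Angstrom.
#' @return Logical; attribute `"rmsd"` carries the two RMSD values.
#' @export
is_c3_symmetric <- function(x, tol = 1e-6) {
  if (n_chains(x) != 3L) return(FALSE)
  if (is.null(x$axis)) return(FALSE)
  ch <- unique(x$atoms$chain)
  A <- as.matrix(x$atoms[x$atoms$chain == ch[1], c("x", "y", "z")])
  rmsds <- vapply(1:2, function(k) {
    Bk <- as.matrix(x$atoms[x$atoms$chain == ch[1 + k], c("x", "y", "z")])
    rot <- rotate_coords(A, x$axis$direction, k * 2 * pi / 3, x$axis$point)
    sqrt(mean(rowSums((rot - Bk)^2)))
  }, numeric(1))
  structure(all(rmsds <= tol), rmsd = rmsds)
}

# Ideal tetrahedral CB reconstruction from backbone N, CA, C (used for
# glycine). Bond length CA-CB 1.53 A.
.reconstruct_cb <- function(N, CA, C) {
  u <- unit_vector(N - CA)
  v <- unit_vector(C - CA)
  bis <- unit_vector(u + v)
  perp <- unit_vector(pracma::cross(u, v))
  theta <- 54.75 * pi / 180
  CA + 1.53 * (-cos(theta) * bis + sin(theta) * perp)
}

#' In-silico cysteine substitution
#'
#' Renames the selected residue to CYS in all chains and places an idealised
#' SG atom: 1.8 A beyond CB along the CA->CB direction. A missing CB (e.g.
#' glycine) is first reconstructed from N, CA, C with ideal tetrahedral
#' geometry (CA-CB 1.53 A). No rotamer sampling is performed; the placement
#' is deterministic, which suffices because the caliper analysis consumes
#' CA-CA distances and uses SG only for S-S span reporting.
#'
#' @param x a `trimer_structure`.
#' @param resno 1-based author residue number to mutate (all chains).
#' @return The mutated `trimer_structure`. A residue that is already CYS
#'   with an SG present is returned unchanged.
#' @export
mutate_to_cys <- function(x, resno) {
  a <- x$atoms
  if (!any(a$resno == resno)) stop("residue ", resno, " absent from structure")
  chains <- unique(a$chain)
  already <- all(vapply(chains, function(ch) {
    r <- a[a$chain == ch & a$resno == resno, ]
    nrow(r) > 0 && all(r$resid == "CYS") && "SG" %in% r$elety
  }, logical(1)))
  if (already) return(x)
  for (ch in chains) {
    sel <- a$chain == ch & a$resno == resno
    r <- a[sel, ]
    get_at <- function(nm) {
      i <- which(r$elety == nm)
      if (!length(i)) return(NULL)
      as.numeric(r[i[1], c("x", "y", "z")])
    }
    CA <- get_at("CA")
    if (is.null(CA)) stop("CA missing for residue ", resno, " chain ", ch)
    CB <- get_at("CB")
    if (is.null(CB)) {
      N <- get_at("N"); C <- get_at("C")
      if (is.null(N) || is.null(C)) {
        stop("cannot reconstruct CB for residue ", resno, " chain ", ch,
             ": backbone N/C missing")
      }
      CB <- .reconstruct_cb(N, CA, C)
      a <- rbind(a, data.frame(chain = ch, resno = resno, resid = "CYS",
                               elety = "CB", x = CB[1], y = CB[2], z = CB[3],
                               stringsAsFactors = FALSE))
    }
    SG <- CB + 1.8 * unit_vector(CB - CA)
    a$resid[a$chain == ch & a$resno == resno] <- "CYS"
    a <- a[!(a$chain == ch & a$resno == resno & a$elety == "SG"), ]
    a <- rbind(a, data.frame(chain = ch, resno = resno, resid = "CYS",
                             elety = "SG", x = SG[1], y = SG[2], z = SG[3],
                             stringsAsFactors = FALSE))
  }
  ord <- order(match(a$chain, chains), a$resno)
  trimer_structure(a[ord, ], symmetric = FALSE, axis = x$axis)
}

#' Inter-chain distances for one atom position
#'
#' Euclidean distances between the selected atom in the three chain pairs
#' (A-B, B-C, A-C in chain storage order) and their minimum — the quantity
#' a bifunctional cross-linker probes between subunits.
#'
#' @param x a three-chain `trimer_structure`.
#' @param resno residue number.
#' @param elety atom name (default `"CA"`).
#' @return List with `pairs` (named length-3 numeric, Angstrom) and `min`.
#' @export
interchain_distances <- function(x, resno, elety = "CA") {
  if (n_chains(x) != 3L) stop("structure must have three chains")
  chains <- unique(x$atoms$chain)
  pos <- lapply(chains, function(ch) {
    r <- x$atoms[x$atoms$chain == ch & x$atoms$resno == resno &
                   x$atoms$elety == elety, ]
    if (nrow(r) == 0) {
      stop("atom ", elety, " of residue ", resno, " missing in chain ", ch)
    }
    as.numeric(r[1, c("x", "y", "z")])
  })
  pr <- rbind(c(1, 2), c(2, 3), c(1, 3))
  d <- apply(pr, 1, function(ij) vec_dist(pos[[ij[1]]], pos[[ij[2]]]))
  names(d) <- apply(pr, 1, function(ij) paste(chains[ij], collapse = "-"))
  list(pairs = d, min = min(d))
}
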