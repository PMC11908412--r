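# Polyproline-II ruler geometry: idealised Cys-(Pro)n-Cys backbones built from
# canonical internal coordinates, written/read as PDB via bio3d.

# Internal coordinate set (Engh & Huber-like averages, Angstroms / degrees).
.bb <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.530, b_CB_SG = 1.810,
  a_C_N_CA = 121.7, a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_CA_C_O = 120.5,
  a_C_CA_CB = 110.1, a_CA_CB_SG = 114.0
)

# PPII dihedrals: canonical textbook values; reproduce the ~3.1 A rise/residue.
.ppii <- list(phi = -75, psi = 145, omega = 180)

.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

deg2rad <- function(x) x * pi / 180

# Natural extension reference frame: position atom D given A-B-C, the bond
# length C-D, the angle B-C-D and the dihedral A-B-C-D (degrees).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an idealised polyproline-II ruler model
#'
#' Constructs a Cys-(Pro)n-Cys peptide with canonical PPII backbone dihedrals
#' (phi = -75, psi = +145, omega = 180 degrees) and ideal bond geometry. The
#' two terminal cysteine Sgamma atoms are the dye attachment sites; `n_pro = 0`
#' yields the minimal Cys-Cys construct. The PPII geometry gives the expected
#' rise of roughly 3.1 Angstroms per residue along the helix axis, which is
#' what makes the series usable as a molecular ruler.
#'
#' @param n_pro Non-negative integer number of proline residues between the
#'   two cysteines.
#' @return An object of class `quench_structure`: a list with `atoms` (a
#'   data.frame with columns `name`, `resno`, `resid`, `element`, `vdw`, `x`,
#'   `y`, `z`), `n_pro`, and `attachment_atoms` (row indices of the two
#'   Sgamma atoms).
#' @examples
#' mod <- build_polyproline(6)
#' sg <- mod$atoms[mod$attachment_atoms, c("x", "y", "z")]
#' sqrt(sum((sg[1, ] - sg[2, ])^2))  # Sg-Sg end-to-end distance
#' @export
build_polyproline <- function(n_pro) {
  stopifnot(length(n_pro) == 1, is.finite(n_pro), n_pro >= 0, n_pro == round(n_pro))
  n_res <- n_pro + 2
  resid <- c("CYS", rep("PRO", n_pro), "CYS")
  b <- .bb

  # backbone N, CA, C per residue
  N <- CA <- C <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b$b_N_CA, 0, 0)
  ang <- deg2rad(b$a_N_CA_C)
  C[1, ] <- CA[1, ] + b$b_CA_C * c(-cos(ang), sin(ang), 0)
  if (n_res > 1) {
    for (i in 2:n_res) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           b$b_C_N, b$a_CA_C_N, .ppii$psi)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            b$b_N_CA, b$a_C_N_CA, .ppii$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           b$b_CA_C, b$a_N_CA_C, .ppii$phi)
    }
  }

  rows <- list()
  add <- function(name, resno, rid, element, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resno = resno, resid = rid, element = element,
      vdw = unname(.vdw_table[element]),
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    add("N", i, resid[i], "N", N[i, ])
    add("CA", i, resid[i], "C", CA[i, ])
    add("C", i, resid[i], "C", C[i, ])
    # carbonyl O anti to the following N (dihedral psi + 180)
    O <- nerf_place(N[i, ], CA[i, ], C[i, ], b$b_C_O, b$a_CA_C_O, .ppii$psi + 180)
    add("O", i, resid[i], "O", O)
    if (i == n_res) {  # C-terminal carboxylate
      OXT <- nerf_place(N[i, ], CA[i, ], C[i, ], b$b_C_O, b$a_CA_C_O, .ppii$psi)
      add("OXT", i, resid[i], "O", OXT)
    }
    # CB via improper dihedral N-C-CA-CB = -122.6 deg (L-amino acids)
    CB <- nerf_place(N[i, ], C[i, ], CA[i, ], b$b_CA_CB, b$a_C_CA_CB, -122.6)
    add("CB", i, resid[i], "C", CB)
    if (resid[i] == "CYS") {
      # chi1 at the most populated cysteine rotamer (gauche-)
      SG <- nerf_place(N[i, ], CA[i, ], CB, b$b_CB_SG, b$a_CA_CB_SG, -60)
      add("SG", i, resid[i], "S", SG)
    } else {
      # proline ring; dihedrals chosen so CD-N closes to the 1.47 A bond
      CG <- nerf_place(N[i, ], CA[i, ], CB, 1.495, 104.5, 14)
      CD <- nerf_place(CA[i, ], CB, CG, 1.507, 106.1, -18)
      add("CG", i, resid[i], "C", CG)
      add("CD", i, resid[i], "C", CD)
    }
  }
  atoms <- do.call(rbind, rows)
  attachment <- which(atoms$name == "SG")
  stopifnot(length(attachment) == 2)
  structure(list(atoms = atoms, n_pro = n_pro, attachment_atoms = attachment),
            class = "quench_structure")
}

#' @export
print.quench_structure <- function(x, ...) {
  cat(sprintf("PPII ruler: Cys-(Pro)%d-Cys, %d atoms, attachment Sg at rows %s\n",
              x$n_pro, nrow(x$atoms),
              paste(x$attachment_atoms, collapse = ", ")))
  invisible(x)
}

#' Write a structure model to a PDB file
#'
#' @param structure A `quench_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  pdb <- bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, elety = a$name,
    chain = rep("A", nrow(a)), elesy = a$element)
  invisible(path)
}

#' Read a structure model from a PDB file
#'
#' Attachment atoms are taken to be all SG atoms of CYS residues.
#'
#' @param path PDB file path.
#' @return A `quench_structure`.
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  element <- ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy),
                    substr(trimws(at$elety), 1, 1))
  atoms <- data.frame(
    name = trimws(at$elety), resno = at$resno, resid = trimws(at$resid),
    element = element,
    vdw = unname(ifelse(element %in% names(.vdw_table),
                        .vdw_table[element], 1.7)),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  attachment <- which(atoms$name == "SG" & atoms$resid == "CYS")
  structure(list(atoms = atoms,
                 n_pro = sum(tapply(atoms$resid, atoms$resno, `[`, 1) == "PRO"),
                 attachment_atoms = attachment),
            class = "quench_structure")
}

#' Distance-per-residue slope of a ruler series
#'
#' Ordinary least-squares slope of inter-dye distance against the number of
#' proline residues. For PPII rulers this recovers the helical rise of
#' roughly 3 Angstroms per residue.
#'
#' @param series Data frame or list of pairs with columns/elements `n_pro`
#'   and `distance` (Angstroms).
#' @return Slope in Angstroms per residue.
#' @export
distance_per_residue_slope <- function(series) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- do.call(rbind, lapply(series, function(p)
      data.frame(n_pro = p[[1]], distance = p[[2]])))
  }
  stopifnot(all(c("n_pro", "distance") %in% names(series)))
  if (length(unique(series$n_pro)) < 2)
    stop("slope undefined: need at least two distinct n_pro values")
  unname(coef(lm(distance ~ n_pro, data = series))[2])
}

#' Probability that a polyproline helix is all-trans
#'
#' Each peptidyl-prolyl bond isomerises to cis with probability `p_cis`
#' independently; the all-trans probability is `(1 - p_cis)^n_bonds`. Whether
#' terminal prolines are counted among the bonds is the caller's choice via
#' `n_bonds`.
#'
#' @param p_cis Per-bond cis probability in `[0, 1]`.
#' @param n_bonds Positive integer number of prolyl bonds counted.
#' @return All-trans probability.
#' @examples
#' all_trans_probability(0.035, 6)  # ~0.81
#' @export
all_trans_probability <- function(p_cis, n_bonds) {
  stopifnot(p_cis >= 0, p_cis <= 1, n_bonds >= 1, n_bonds == round(n_bonds))
  (1 - p_cis)^n_bonds
}

#' Helical rise per residue from a Calpha trace
#'
#' Fits the helix axis as the dominant singular vector of the centred Calpha
#' coordinates and returns the mean projected displacement between
#' consecutive Calpha atoms.
#'
#' @param structure A `quench_structure` with at least 3 residues.
#' @return Rise in Angstroms per residue.
#' @export
helix_rise_per_residue <- function(structure) {
  ca <- as.matrix(structure$atoms[structure$atoms$name == "CA", c("x", "y", "z")])
  stopifnot(nrow(ca) >= 3)
  cc <- scale(ca, center = TRUE, scale = FALSE)
  axis <- svd(cc)$v[, 1]
  steps <- diff(ca %*% axis)
  mean(abs(steps))
}
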