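# ideal backbone geometry (Angstrom / degrees)
.geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              omega = 180)

unit3 <- function(v) v / sqrt(sum(v^2))

# NeRF placement: position of atom d given chain a-b-c, the b-c-d bond
# angle (deg), the c-d bond length and the a-b-c-d dihedral (rad)
place_atom <- function(a, b, c, bond, angle_deg, torsion) {
  th <- angle_deg * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(matrix(b - a, 1, 3), matrix(bc, 1, 3))[1, ])
  m <- cross3(matrix(n, 1, 3), matrix(bc, 1, 3))[1, ]
  c + bond * (-cos(th) * bc + sin(th) * (cos(torsion) * m + sin(torsion) * n))
}

#' Build an ideal-geometry polyalanine-like backbone
#'
#' Constructs N, CA, C backbone coordinates for a chain with fixed ideal
#' bond lengths and angles, trans peptide bonds, and the supplied phi/psi
#' torsions. phi[1] and psi[n] do not enter the construction.
#'
#' @param phi,psi Torsion angles in radians, length n (number of residues).
#' @return An \code{atomic_model} with 3 atoms per residue (N, CA, C;
#'   elements N, C, C), occupancy 1, B = 10.
#' @examples
#' m <- build_backbone(rep(-1.05, 8), rep(-0.79, 8))  # helix-like
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- .geom
  xyz <- matrix(0, 3 * n, 3)
  aN <- function(i) 3 * (i - 1) + 1
  aCA <- function(i) 3 * (i - 1) + 2
  aC <- function(i) 3 * (i - 1) + 3
  ang <- g$a_n_ca_c * pi / 180
  xyz[aN(1), ] <- c(0, 0, 0)
  xyz[aCA(1), ] <- c(g$b_n_ca, 0, 0)
  xyz[aC(1), ] <- xyz[aCA(1), ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  om <- g$omega * pi / 180
  for (i in 2:n) {
    xyz[aN(i), ] <- place_atom(xyz[aN(i - 1), ], xyz[aCA(i - 1), ], xyz[aC(i - 1), ],
                               g$b_c_n, g$a_ca_c_n, psi[i - 1])
    xyz[aCA(i), ] <- place_atom(xyz[aCA(i - 1), ], xyz[aC(i - 1), ], xyz[aN(i), ],
                                g$b_n_ca, g$a_c_n_ca, om)
    xyz[aC(i), ] <- place_atom(xyz[aC(i - 1), ], xyz[aN(i), ], xyz[aCA(i), ],
                               g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  atomic_model(xyz,
               element = rep(c("N", "C", "C"), n),
               b = 10,
               resno = rep(seq_len(n), each = 3),
               atom_name = rep(c("N", "CA", "C"), n))
}

#' Pull a coordinate gradient back to backbone torsions
#'
#' Given dL/dX for the atoms of a \code{\link{build_backbone}} chain,
#' returns dL/dphi and dL/dpsi using the exact rotating-bond rule: a
#' torsion rotates every downstream atom rigidly about its bond axis, so
#' dL/dtheta = sum_j u . ((x_j - pivot) x g_j) over affected atoms.
#'
#' @param xyz Coordinates of the chain, (3n) x 3, atoms ordered N, CA, C
#'   per residue.
#' @param g Gradient dL/dX, same shape.
#' @return List with \code{dphi}, \code{dpsi} (length n; entries 1 and n
#'   respectively are zero).
#' @export
backbone_torsion_grad <- function(xyz, g) {
  n <- nrow(xyz) / 3
  dphi <- numeric(n); dpsi <- numeric(n)
  aN <- function(i) 3 * (i - 1) + 1
  aCA <- function(i) 3 * (i - 1) + 2
  aC <- function(i) 3 * (i - 1) + 3
  for (i in seq_len(n)) {
    if (i >= 2) {
      # phi_i: axis N_i -> CA_i, pivot CA_i, affects C_i and residues > i
      u <- unit3(xyz[aCA(i), ] - xyz[aN(i), ])
      p <- xyz[aCA(i), ]
      idx <- c(aC(i), if (i < n) (3 * i + 1):(3 * n))
      r <- sweep(xyz[idx, , drop = FALSE], 2, p)
      dphi[i] <- sum(u * colSums(cross3(r, g[idx, , drop = FALSE])))
    }
    if (i <= n - 1) {
      # psi_i: axis CA_i -> C_i, pivot C_i, affects residues > i
      u <- unit3(xyz[aC(i), ] - xyz[aCA(i), ])
      p <- xyz[aC(i), ]
      idx <- (3 * i + 1):(3 * n)
      r <- sweep(xyz[idx, , drop = FALSE], 2, p)
      dpsi[i] <- sum(u * colSums(cross3(r, g[idx, , drop = FALSE])))
    }
  }
  list(dphi = dphi, dpsi = dpsi)
}

#' Calpha coordinates of a backbone model
#'
#' @param model An \code{atomic_model} with CA atoms named "CA".
#' @return Matrix of CA coordinates, one row per residue.
#' @export
ca_coords <- function(model) {
  model_xyz(model)[model$atom_name == "CA", , drop = FALSE]
}

#' Calpha r.m.s.d. between two models after optimal superposition
#'
#' @param model_a,model_b Atomic models with matching CA atoms.
#' @param superpose Superpose first (default TRUE)?
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model_a, model_b, superpose = TRUE) {
  xa <- ca_coords(model_a); xb <- ca_coords(model_b)
  stopifnot(nrow(xa) == nrow(xb))
  if (superpose) xa <- weighted_kabsch(xa, xb)$x_aligned
  sqrt(mean(rowSums((xa - xb)^2)))
}
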