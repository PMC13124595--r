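#' Read an atomic model from a PDB file
#'
#' Thin wrapper over bio3d's PDB parser producing the package's
#' \code{atomic_model}. Residues missing a Calpha atom are kept but
#' flagged with a warning (they are excluded from alignment sets by the
#' callers that need Calphas).
#'
#' @param path PDB file path.
#' @return An \code{atomic_model}.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(trimws(at$elety), 1, 1)
  }
  el <- trimws(el)
  m <- atomic_model(cbind(at$x, at$y, at$z), element = el,
                    occ = ifelse(is.na(at$o), 1, pmin(pmax(at$o, 1e-6), 1)),
                    b = ifelse(is.na(at$b), 10, pmax(at$b, 0)),
                    resno = at$resno, atom_name = trimws(at$elety),
                    chain = ifelse(is.na(at$chain), "A", at$chain))
  res_has_ca <- tapply(m$atom_name == "CA", m$resno, any)
  if (any(!res_has_ca))
    warning("residue(s) without CA: ",
            paste(names(res_has_ca)[!res_has_ca], collapse = ", "))
  m
}

#' Write an atomic model to a PDB file
#'
#' @param model An \code{atomic_model}.
#' @param path Output path.
#' @param resid Residue name used for all residues (default "ALA").
#' @return Invisibly, the path.
#' @export
write_model <- function(model, path, resid = "ALA") {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model_xyz(model))),
                   resno = model$resno,
                   resid = rep_len(resid, nrow(model)),
                   eleno = seq_len(nrow(model)),
                   elety = model$atom_name,
                   chain = model$chain,
                   o = model$occ, b = model$b,
                   elesy = model$element)
  invisible(path)
}

#' Write a reflection set as a reflection CIF file
#'
#' Emits a minimal self-contained reflection CIF: cell and symmetry
#' blocks plus a _refln loop with Miller indices, intensities, sigmas,
#' the free-set status ('f' free / 'o' working) and, when present,
#' E_e/D_obs columns.
#'
#' @param refl A reflection set with \code{I_o}, \code{sigma_I} (and
#'   optionally \code{E_e}, \code{D_obs}, \code{free_flag}).
#' @param cell The \code{unit_cell}.
#' @param path Output path.
#' @param spacegroup Space-group name recorded in the file (default "P 1").
#' @return Invisibly, the path.
#' @export
write_reflections <- function(refl, cell, path, spacegroup = "P 1") {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("data_llgrefine")
  wl("_cell.length_a    %.4f", cell$a)
  wl("_cell.length_b    %.4f", cell$b)
  wl("_cell.length_c    %.4f", cell$c)
  wl("_cell.angle_alpha %.4f", cell$alpha)
  wl("_cell.angle_beta  %.4f", cell$beta)
  wl("_cell.angle_gamma %.4f", cell$gamma)
  wl("_symmetry.space_group_name_H-M '%s'", spacegroup)
  wl("loop_")
  cols <- c("_refln.index_h", "_refln.index_k", "_refln.index_l",
            "_refln.intensity_meas", "_refln.intensity_sigma",
            "_refln.status")
  has_ed <- !is.null(refl$E_e) && !is.null(refl$D_obs)
  if (has_ed) cols <- c(cols, "_refln.pdbx_E_e", "_refln.pdbx_D_obs")
  writeLines(cols, con)
  free <- if (!is.null(refl$free_flag)) ifelse(refl$free_flag, "f", "o")
          else rep("o", nrow(refl))
  rows <- sprintf("%d %d %d %.6g %.6g %s", refl$h, refl$k, refl$l,
                  refl$I_o, refl$sigma_I, free)
  if (has_ed) rows <- paste(rows, sprintf("%.6g %.6g", refl$E_e, refl$D_obs))
  writeLines(rows, con)
  invisible(path)
}

#' Read a reflection CIF file
#'
#' Parses the _refln loop of a reflection CIF, resolving intensity and
#' sigma columns by configurable names, and rebuilds a full reflection set
#' (resolution, centricity, epsilon, bins, free flags, effective
#' amplitudes). Precomputed E_e/D_obs columns are honored verbatim when
#' present.
#'
#' @param path File path.
#' @param cols Column-name map; defaults follow the writer:
#'   \code{list(I = "_refln.intensity_meas", sigI = "_refln.intensity_sigma",
#'   status = "_refln.status", E_e = "_refln.pdbx_E_e",
#'   D_obs = "_refln.pdbx_D_obs")}.
#' @param spacegroup Space-group operators (default from the file's
#'   symmetry record when recognized, else P1).
#' @param n_bins Resolution bins (default 10).
#' @return List: \code{refl} (reflection set), \code{cell}.
#' @export
read_reflections <- function(path, cols = list(), spacegroup = NULL,
                             n_bins = 10) {
  defaults <- list(I = "_refln.intensity_meas",
                   sigI = "_refln.intensity_sigma",
                   status = "_refln.status",
                   E_e = "_refln.pdbx_E_e", D_obs = "_refln.pdbx_D_obs")
  cols <- utils::modifyList(defaults, cols)
  ln <- readLines(path)
  getnum <- function(tag) {
    i <- grep(paste0("^", tag, "\\b"), ln)
    if (!length(i)) stop("missing ", tag, " in ", path)
    as.numeric(strsplit(trimws(ln[i[1]]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(getnum("_cell.length_a"), getnum("_cell.length_b"),
                    getnum("_cell.length_c"), getnum("_cell.angle_alpha"),
                    getnum("_cell.angle_beta"), getnum("_cell.angle_gamma"))
  if (is.null(spacegroup)) {
    i <- grep("^_symmetry.space_group_name", ln)
    sg_name <- if (length(i)) gsub("[ ']", "", sub("^\\S+\\s+", "", ln[i[1]])) else "P1"
    spacegroup <- tryCatch(spacegroup_ops(sg_name),
                           error = function(e) spacegroup_ops("P1"))
  }
  loop_i <- grep("^\\s*loop_\\s*$", ln)
  if (!length(loop_i)) stop("no loop_ block in ", path)
  hdr_start <- loop_i[1] + 1
  hdr <- character()
  i <- hdr_start
  while (i <= length(ln) && grepl("^\\s*_", ln[i])) {
    hdr <- c(hdr, trimws(ln[i])); i <- i + 1
  }
  need <- c(cols$I, cols$sigI)
  miss <- setdiff(need, hdr)
  if (length(miss))
    stop("missing reflection column(s): ", paste(miss, collapse = ", "),
         " (column map: I = ", cols$I, ", sigI = ", cols$sigI, ")")
  body <- ln[i:length(ln)]
  body <- body[!grepl("^\\s*(#|$|data_|loop_)", body)]
  toks <- strsplit(trimws(body), "\\s+")
  nc <- length(hdr)
  bad <- which(vapply(toks, length, integer(1)) != nc)
  if (length(bad)) stop("malformed reflection row at line ",
                        i + bad[1] - 1, " of ", path)
  tab <- do.call(rbind, toks)
  colnames(tab) <- hdr
  hkl <- cbind(as.integer(tab[, "_refln.index_h"]),
               as.integer(tab[, "_refln.index_k"]),
               as.integer(tab[, "_refln.index_l"]))
  refl <- reflection_metadata(cell, spacegroup, hkl)
  refl <- assign_bins(refl, n_bins = n_bins)
  refl$I_o <- as.numeric(tab[, cols$I])
  refl$sigma_I <- as.numeric(tab[, cols$sigI])
  if (cols$status %in% hdr) {
    refl$free_flag <- tab[, cols$status] == "f"
  } else {
    refl$free_flag <- rep(FALSE, nrow(refl))
  }
  if (cols$E_e %in% hdr && cols$D_obs %in% hdr) {
    refl$E_e <- as.numeric(tab[, cols$E_e])
    refl$D_obs <- as.numeric(tab[, cols$D_obs])
  } else {
    ea <- effective_amplitudes(refl$I_o, refl$sigma_I, refl)
    refl$E_e <- ea$E_e
    refl$D_obs <- ea$D_obs
  }
  list(refl = refl, cell = cell)
}

#' Write a density map in MRC format
#'
#' Mode-2 (float32) MRC with voxel size encoded in the cell record and the
#' origin in the ORIGIN header words; round-trips bit-exactly through
#' \code{\link{read_map}} up to float32 storage of the density values.
#'
#' @param map A \code{density_map}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_map <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nstart
  wi(d)                      # mx my mz
  wf(d * map$voxel)          # cell lengths
  wf(c(90, 90, 90))          # cell angles
  wi(c(1, 2, 3))             # axis order
  g <- as.numeric(map$grid)
  wf(c(min(g), max(g), mean(g)))
  wi(c(1, 0))                # ispg, nsymbt
  wi(rep(0, 25))             # extra words 25..49
  wf(map$origin)             # origin x y z (words 50..52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp LE
  wf(stats::sd(g))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(g)
  invisible(path)
}

#' Read an MRC density map
#'
#' Supports mode-2 maps; axis-order permutations are normalized to x, y, z
#' with a message.
#'
#' @param path File path.
#' @return A \code{density_map}.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  ri(3)                      # nstart
  m <- ri(3)                 # mx my mz
  cella <- rf(3)
  rf(3)                      # angles
  axes <- ri(3)
  rf(3)                      # dmin dmax dmean
  ri(2)                      # ispg nsymbt
  ri(25)                     # extra
  origin <- rf(3)
  readChar(con, 4)           # MAP
  readBin(con, "raw", 4)     # machst
  rf(1)                      # rms
  ri(1)                      # nlabl
  readBin(con, "raw", 800)
  g <- array(rf(prod(d)), d)
  if (!identical(axes, c(1L, 2L, 3L))) {
    message("normalizing MRC axis order ", paste(axes, collapse = ","))
    perm <- order(axes)
    g <- aperm(g, perm)
    d <- dim(g)
  }
  voxel <- cella / m
  density_map(g, voxel = voxel, origin = origin)
}

#' Write a cluster profile as a plain-text array
#'
#' Simple text container: a dims header line followed by one line per
#' cluster/residue column of symbol values at full double precision.
#'
#' @param m Profile array (clusters x residues x symbols).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(m, path) {
  dm <- dim(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("profile %d %d %d", dm[1], dm[2], dm[3]), con)
  for (k in seq_len(dm[1])) for (l in seq_len(dm[2]))
    writeLines(paste(format(m[k, l, ], digits = 17), collapse = " "), con)
  invisible(path)
}

#' Read a cluster profile written by \code{\link{write_profile}}
#'
#' @param path File path.
#' @return The profile array.
#' @export
read_profile <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(ln[1], "\\s+")[[1]]
  if (hd[1] != "profile") stop("not a profile file: ", path)
  dm <- as.integer(hd[2:4])
  vals <- as.numeric(unlist(strsplit(trimws(ln[-1]), "\\s+")))
  if (length(vals) != prod(dm)) stop("profile size mismatch in ", path)
  m <- array(0, dm)
  i <- 1
  for (k in seq_len(dm[1])) for (l in seq_len(dm[2])) {
    m[k, l, ] <- vals[i:(i + dm[3] - 1)]
    i <- i + dm[3]
  }
  m
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration mirrors \code{\link{refinement_config}} plus file
#' paths and output options; unknown keys are preserved so the file
#' round-trips losslessly.
#'
#' @param path YAML file path.
#' @return For \code{read_run_config}, the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
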