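#' Conformational ensemble of a Lennard-Jones matrix
#'
#' Frames of site coordinates plus per-site LJ parameters and an
#' orthorhombic box — the material the probe is inserted into.
#'
#' @param coords numeric array \code{[n_sites, 3, n_frames]} of positions (A).
#' @param epsilon,sigma per-site LJ well depth (kJ/mol) and diameter (A).
#' @param box_lengths numeric(3), orthorhombic box edges (A).
#' @param frame_weights optional non-negative weights, normalized to sum 1;
#'   default uniform.
#' @return An object of class \code{conformation_ensemble}.
#' @export
conformation_ensemble <- function(coords, epsilon, sigma, box_lengths,
                                  frame_weights = NULL) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  .assert(length(dim(coords)) == 3 && dim(coords)[2] == 3,
          "coords must be an [n_sites, 3, n_frames] array")
  ns <- dim(coords)[1]; nf <- dim(coords)[3]
  .assert(all(is.finite(coords)), "coordinates must be finite")
  .assert(length(epsilon) == ns && length(sigma) == ns,
          "need one (epsilon, sigma) pair per site")
  .assert(all(epsilon >= 0), "epsilon must be >= 0")
  .assert(all(sigma > 0), "sigma must be > 0")
  box_lengths <- rep_len(as.numeric(box_lengths), 3)
  .assert(all(box_lengths > 0), "box_lengths must be > 0")
  if (is.null(frame_weights)) frame_weights <- rep(1 / nf, nf)
  .assert(length(frame_weights) == nf && all(frame_weights >= 0) &&
            sum(frame_weights) > 0, "frame_weights must be >= 0, length n_frames")
  frame_weights <- frame_weights / sum(frame_weights)
  structure(list(coords = coords, epsilon = as.numeric(epsilon),
                 sigma = as.numeric(sigma), box_lengths = box_lengths,
                 frame_weights = frame_weights, n_frames = nf,
                 n_sites = ns),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("conformation_ensemble:", x$n_frames, "frames x", x$n_sites,
      "LJ sites, box", paste(signif(x$box_lengths, 4), collapse = " x "),
      "A\n")
  invisible(x)
}

# subset frames, preserving relative weights
ensemble_subset <- function(ensemble, frames) {
  conformation_ensemble(ensemble$coords[, , frames, drop = FALSE],
                        ensemble$epsilon, ensemble$sigma,
                        ensemble$box_lengths,
                        ensemble$frame_weights[frames])
}

# ---- superposition -------------------------------------------------------

# Kabsch least-squares fit of x onto y (both n x 3): y ~ x %*% R + t
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fitted <- sweep(xc %*% R, 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Superpose ensemble frames onto a reference structure
#'
#' Rigid-body least-squares (Kabsch) fit of each frame onto a reference
#' using a subset of sites (the analogue of fitting trajectory frames on
#' C-alpha atoms before insertion mapping). All sites of the frame are
#' transformed, not only the fitted subset.
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param reference n_sites x 3 (or subset-length x 3) reference positions (A).
#' @param fit_subset integer indices of the sites used for the fit; the
#'   reference must either cover all sites or exactly the subset.
#' @return list with elements \code{ensemble} (fitted) and \code{fits}
#'   (data frame: frame, rmsd, plus rotation/translation in a list column).
#' @export
superpose_frames <- function(ensemble, reference,
                             fit_subset = seq_len(ensemble$n_sites)) {
  .assert(inherits(ensemble, "conformation_ensemble"),
          "ensemble must be a conformation_ensemble")
  fit_subset <- as.integer(fit_subset)
  .assert(length(fit_subset) >= 3, "fit_subset must contain >= 3 sites")
  reference <- as.matrix(reference)
  if (nrow(reference) == ensemble$n_sites) {
    ref_sub <- reference[fit_subset, , drop = FALSE]
  } else if (nrow(reference) == length(fit_subset)) {
    ref_sub <- reference
  } else stop("reference must have n_sites or length(fit_subset) rows")
  # degenerate subset: all singular values of the centered subset must be
  # comfortably nonzero in at least 2 directions (non-collinear)
  sv <- svd(scale(ref_sub, scale = FALSE))$d
  .assert(sv[2] > 1e-8 * max(sv[1], 1),
          "fit_subset reference positions are collinear or degenerate")
  out <- ensemble$coords
  fits <- vector("list", ensemble$n_frames)
  for (f in seq_len(ensemble$n_frames)) {
    fr <- ensemble$coords[, , f]
    k <- kabsch(fr[fit_subset, , drop = FALSE], ref_sub)
    out[, , f] <- sweep(fr %*% k$rotation, 2, k$translation, "+")
    fits[[f]] <- k
  }
  list(ensemble = conformation_ensemble(out, ensemble$epsilon,
                                        ensemble$sigma,
                                        ensemble$box_lengths,
                                        ensemble$frame_weights),
       fits = data.frame(frame = seq_len(ensemble$n_frames),
                         rmsd = vapply(fits, `[[`, numeric(1), "rmsd"),
                         transform = I(fits)))
}

# ---- file formats --------------------------------------------------------

#' Write an ensemble to disk
#'
#' Coordinates go to a multi-model PDB (via bio3d) or a concatenated XYZ
#' stack; LJ parameters go to a plain-text sidecar table with columns
#' \code{site_id}, \code{epsilon}, \code{sigma} (first row holds the box).
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param path coordinate file (.pdb or .xyz).
#' @param lj_path sidecar LJ table; default \code{paste0(path, ".lj")}.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(ensemble, path, lj_path = paste0(path, ".lj")) {
  ns <- ensemble$n_sites; nf <- ensemble$n_frames
  xyz <- t(apply(ensemble$coords, 3, function(fr) as.vector(t(fr))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", ns),
                     resno = seq_len(ns), resid = rep("SIT", ns),
                     elety = rep("C", ns))
  } else if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nf)) {
      writeLines(c(as.character(ns), sprintf("frame %d", f)), con)
      fr <- ensemble$coords[, , f]
      writeLines(sprintf("C %.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
    }
  } else stop("unsupported ensemble format (use .pdb or .xyz): ", path)
  hdr <- sprintf("# box %.9g %.9g %.9g", ensemble$box_lengths[1],
                 ensemble$box_lengths[2], ensemble$box_lengths[3])
  tab <- data.frame(site_id = seq_len(ns), epsilon = ensemble$epsilon,
                    sigma = ensemble$sigma)
  writeLines(c(hdr, "site_id epsilon sigma",
               sprintf("%d %.9g %.9g", tab$site_id, tab$epsilon, tab$sigma)),
             lj_path)
  invisible(path)
}

#' Read an ensemble from disk
#'
#' @param path multi-model PDB or concatenated XYZ stack (A).
#' @param lj_path sidecar LJ table written by \code{\link{write_ensemble}}.
#' @return a \code{conformation_ensemble}.
#' @export
read_ensemble <- function(path, lj_path = paste0(path, ".lj")) {
  .assert(file.exists(path), paste("no such file:", path))
  .assert(file.exists(lj_path), paste("missing LJ sidecar table:", lj_path))
  lj_lines <- readLines(lj_path)
  boxline <- grep("^# box ", lj_lines, value = TRUE)
  .assert(length(boxline) == 1, "LJ sidecar lacks a '# box' header line")
  box <- as.numeric(strsplit(sub("^# box ", "", boxline), " +")[[1]])
  tab <- utils::read.table(text = lj_lines[!grepl("^#", lj_lines)],
                           header = TRUE)
  .assert(all(c("site_id", "epsilon", "sigma") %in% names(tab)),
          "LJ sidecar must have columns site_id, epsilon, sigma")
  tab <- tab[order(tab$site_id), ]
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nf <- nrow(p$xyz)
    ns <- ncol(p$xyz) / 3
    coords <- array(NA_real_, c(ns, 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(p$xyz[f, ], ncol = 3, byrow = TRUE)
  } else if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    frames <- list(); i <- 1; fidx <- 0
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      fidx <- fidx + 1
      .assert(!is.na(n) && n > 0,
              sprintf("malformed XYZ header at line %d (frame %d)", i, fidx))
      .assert(i + 1 + n <= length(lines),
              sprintf("truncated XYZ frame %d at line %d", fidx, i))
      rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "[ \t]+")
      frames[[fidx]] <- t(vapply(rows, function(r) as.numeric(r[2:4]),
                                 numeric(3)))
      i <- i + 2 + n
    }
    ns_all <- vapply(frames, nrow, integer(1))
    .assert(length(unique(ns_all)) == 1,
            sprintf("inconsistent atom counts across XYZ frames (frame %d has %d, frame 1 has %d)",
                    which(ns_all != ns_all[1])[1],
                    ns_all[which(ns_all != ns_all[1])[1]], ns_all[1]))
    coords <- array(unlist(lapply(frames, t)), c(3, ns_all[1],
                                                 length(frames)))
    coords <- aperm(coords, c(2, 1, 3))
  } else stop("unsupported ensemble format (use .pdb or .xyz): ", path)
  .assert(dim(coords)[1] == nrow(tab),
          sprintf("LJ sidecar has %d sites but coordinate file has %d",
                  nrow(tab), dim(coords)[1]))
  conformation_ensemble(coords, tab$epsilon, tab$sigma, box)
}
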