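#' Neuron morphologies for the reduced FSI model
#'
#' A morphology is a rooted tree of cylindrical sections: one soma section
#' plus unbranched or branched dendritic sections.  Positions along a section
#' are measured in micrometres from the proximal end; "distance from soma"
#' means path distance from the soma-dendrite junction.
#'
#' @param sections data.frame with columns `id`, `parent_id` (NA for the
#'   soma), `type` (`"soma"` or `"dendrite"`), `length` and `diameter`
#'   (micrometres).
#' @return An object of class `fsi_morphology`.
#' @export
fsi_morphology <- function(sections) {
  stopifnot(is.data.frame(sections))
  need <- c("id", "parent_id", "type", "length", "diameter")
  if (!all(need %in% names(sections)))
    stop("sections must have columns: ", paste(need, collapse = ", "))
  if (any(sections$length <= 0) || any(sections$diameter <= 0))
    stop("all section lengths and diameters must be > 0")
  if (sum(sections$type == "soma") != 1L)
    stop("exactly one soma section required")
  soma_id <- sections$id[sections$type == "soma"]
  if (!is.na(sections$parent_id[sections$type == "soma"]))
    stop("the soma must be the root (parent_id NA)")
  kids <- sections[sections$type != "soma", ]
  if (nrow(kids) > 0) {
    if (any(is.na(kids$parent_id)))
      stop("non-soma sections must have a parent")
    if (!all(kids$parent_id %in% sections$id))
      stop("parent_id refers to an unknown section")
    # walk to the root from every section; a revisit means a cycle
    for (i in seq_len(nrow(sections))) {
      seen <- integer(0)
      cur <- sections$id[i]
      while (!is.na(cur)) {
        if (cur %in% seen) stop("cyclic parent links in morphology")
        seen <- c(seen, cur)
        cur <- sections$parent_id[match(cur, sections$id)]
      }
    }
  }
  structure(list(sections = sections, soma_id = soma_id),
            class = "fsi_morphology")
}

#' @export
print.fsi_morphology <- function(x, ...) {
  nd <- sum(x$sections$type == "dendrite")
  cat("FSI morphology:", nd, "dendritic section(s), total cable length",
      format(sum(x$sections$length[x$sections$type == "dendrite"])),
      "um\n")
  invisible(x)
}

#' Build the reduced stand-in FSI morphology
#'
#' A soma cylinder with `n_dendrites` unbranched dendrites attached.  The
#' defaults give a total dendritic length of 3000 um at 1.5 um diameter,
#' typical for a cortical basket cell, and always admit a synapse site
#' 96 um from the soma on the first dendrite.
#'
#' @param n_dendrites number of unbranched dendrites (> 0).
#' @param dendrite_length,dendrite_diameter dendrite dimensions, um.
#' @param soma_length,soma_diameter soma cylinder dimensions, um.
#' @return An `fsi_morphology`.
#' @export
build_reduced_fsi <- function(n_dendrites = 8, dendrite_length = 375,
                              dendrite_diameter = 1.5,
                              soma_length = 20, soma_diameter = 20) {
  if (n_dendrites < 1) stop("n_dendrites must be >= 1 (synapse placement impossible)")
  stopifnot(dendrite_length > 0, dendrite_diameter > 0,
            soma_length > 0, soma_diameter > 0)
  sections <- data.frame(
    id = seq_len(n_dendrites + 1L),
    parent_id = c(NA_integer_, rep(1L, n_dendrites)),
    type = c("soma", rep("dendrite", n_dendrites)),
    length = c(soma_length, rep(dendrite_length, n_dendrites)),
    diameter = c(soma_diameter, rep(dendrite_diameter, n_dendrites)),
    stringsAsFactors = FALSE
  )
  fsi_morphology(sections)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`index type x y z radius parent`), `#` comments.
#' Only types 1 (soma) and 3 (basal dendrite) are honoured; other types are
#' rejected.  Section lengths come from 3D sample coordinates; the segment
#' from a soma sample to the first sample of a daughter dendrite counts
#' toward that dendrite's length.  Dendritic trees are split into
#' unbranched sections at branch points.
#'
#' @param path SWC file path.
#' @return An `fsi_morphology`.
#' @export
load_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("SWC file contains no samples")
  mat <- matrix(NA_real_, nrow = length(lines), ncol = 7)
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 7 || anyNA(f))
      stop("malformed SWC line ", lineno[i], ": ", lines[i])
    mat[i, ] <- f
  }
  idx <- as.integer(mat[, 1]); typ <- as.integer(mat[, 2])
  xyz <- mat[, 3:5, drop = FALSE]; rad <- mat[, 6]; par <- as.integer(mat[, 7])
  if (anyDuplicated(idx)) stop("duplicate SWC sample index")
  if (!all(typ %in% c(1L, 3L)))
    stop("unsupported SWC sample type (only 1 = soma, 3 = basal dendrite)")
  pos <- match(par, idx)          # row of each parent; NA for roots (-1)
  root <- par == -1L
  if (sum(root) != 1L) stop("SWC must have exactly one root sample")
  if (typ[which(root)] != 1L) stop("SWC root sample must be soma (type 1)")
  bad <- !root & (is.na(pos) | pos >= seq_along(idx))
  if (any(bad))
    stop("SWC sample ", idx[which(bad)[1]],
         " has a parent referencing a later or unknown sample")

  seglen <- rep(0, length(idx))
  seglen[!root] <- sqrt(rowSums((xyz[!root, , drop = FALSE] -
                                 xyz[pos[!root], , drop = FALSE])^2))

  soma_rows <- which(typ == 1L)
  soma_len <- sum(seglen[soma_rows])
  soma_diam <- mean(2 * rad[soma_rows])
  if (soma_len <= 0) soma_len <- soma_diam  # single-sample (spherical) soma

  dend <- which(typ == 3L)
  nchild <- tabulate(pos[!is.na(pos)], nbins = length(idx))
  # a dendrite sample starts a new section if its parent is soma or a branch point
  sec_of <- rep(NA_integer_, length(idx))
  secs <- list()
  for (r in dend) {
    p <- pos[r]
    new_sec <- typ[p] == 1L || nchild[p] > 1L
    if (new_sec) {
      parent_sec <- if (typ[p] == 1L) 0L else sec_of[p]
      secs[[length(secs) + 1L]] <- list(parent = parent_sec, rows = r)
      sec_of[r] <- length(secs)
    } else {
      s <- sec_of[p]
      if (is.na(s)) stop("SWC structure error at sample ", idx[r])
      secs[[s]]$rows <- c(secs[[s]]$rows, r)
      sec_of[r] <- s
    }
  }
  n_sec <- length(secs)
  sections <- data.frame(
    id = 1L, parent_id = NA_integer_, type = "soma",
    length = soma_len, diameter = soma_diam, stringsAsFactors = FALSE)
  if (n_sec > 0) {
    dl <- vapply(secs, function(s) sum(seglen[s$rows]), 0)
    dd <- vapply(secs, function(s) mean(2 * rad[s$rows]), 0)
    dp <- vapply(secs, function(s) s$parent + 1L, 0L)  # 0 -> soma id 1
    sections <- rbind(sections, data.frame(
      id = seq_len(n_sec) + 1L, parent_id = as.integer(dp),
      type = "dendrite", length = dl, diameter = dd,
      stringsAsFactors = FALSE))
  }
  fsi_morphology(sections)
}

#' Write a morphology to SWC (internal serialization)
#'
#' Lays sections out on straight lines in distinct directions; branching
#' topology and total cable length round-trip through [load_swc()].  Note
#' that SWC has no notion of a section boundary inside an unbranched
#' chain, so consecutive single-child sections merge into one on re-read
#' (standard SWC semantics); at branch points the structure is preserved.
#'
#' @param morph an `fsi_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "fsi_morphology"))
  secs <- morph$sections
  soma <- secs[secs$type == "soma", ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by fsikir", con)
  fmt <- function(i, t, p3, r, par)
    sprintf("%d %d %.9f %.9f %.9f %.9f %d", i, t, p3[1], p3[2], p3[3], r, par)
  # soma as three collinear samples along z: total path length = soma length
  rs <- soma$diameter / 2
  writeLines(fmt(1L, 1L, c(0, 0, 0), rs, -1L), con)
  writeLines(fmt(2L, 1L, c(0, 0, soma$length / 2), rs, 1L), con)
  writeLines(fmt(3L, 1L, c(0, 0, -soma$length / 2), rs, 1L), con)
  nxt <- 4L
  dend <- secs[secs$type == "dendrite", , drop = FALSE]
  tip_sample <- c(); tip_xyz <- list()  # per section id
  for (i in seq_len(nrow(dend))) {
    s <- dend[i, ]
    # deterministic distinct direction per section
    ang <- 2.399963 * s$id   # golden angle spacing
    zc <- cos(0.7 * s$id)
    dir <- c(sqrt(max(0, 1 - zc^2)) * cos(ang), sqrt(max(0, 1 - zc^2)) * sin(ang), zc)
    dir <- dir / sqrt(sum(dir^2))
    if (s$parent_id == morph$soma_id) {
      par_samp <- 1L; origin <- c(0, 0, 0)
    } else {
      par_samp <- tip_sample[[as.character(s$parent_id)]]
      origin <- tip_xyz[[as.character(s$parent_id)]]
    }
    p <- origin + dir * s$length
    writeLines(fmt(nxt, 3L, p, s$diameter / 2, par_samp), con)
    tip_sample[[as.character(s$id)]] <- nxt
    tip_xyz[[as.character(s$id)]] <- p
    nxt <- nxt + 1L
  }
  invisible(path)
}

#' Discretize a morphology into a compartment tree
#'
#' Each section is split into `ceiling(length / max_len)` equal
#' compartments.  The per-compartment axial resistance to its parent is
#' `Ra * L / (pi * d^2 / 4)` in consistent units (MOhm).  Dendrites attach
#' to the soma compartment whose span contains the soma midpoint.
#'
#' @param morph an `fsi_morphology`.
#' @param max_len maximum compartment length, um.
#' @param ra axial resistivity, Ohm cm (default 172).
#' @return An object of class `fsi_comptree`: a data.frame of compartments
#'   (`index`, `parent`, `section_id`, `pos` = centre position along the
#'   section, `length`, `diameter`, `area` um^2, `r_axial` MOhm, `path_dist`
#'   um from the soma-dendrite junction, `is_soma`) with attribute `ra`.
#' @export
discretize <- function(morph, max_len = 10, ra = 172) {
  stopifnot(inherits(morph, "fsi_morphology"), max_len > 0, ra > 0)
  secs <- morph$sections
  # order sections parent-before-child
  ord <- integer(0)
  pending <- secs$id
  while (length(pending) > 0) {
    ready <- pending[is.na(secs$parent_id[match(pending, secs$id)]) |
                     secs$parent_id[match(pending, secs$id)] %in% ord]
    ord <- c(ord, ready)
    pending <- setdiff(pending, ready)
  }
  rows <- list()
  sec_first <- sec_last <- integer(0)  # first/last compartment per section id
  sec_root_dist <- numeric(0)          # path distance at section origin
  nxt <- 1L
  for (sid in ord) {
    s <- secs[match(sid, secs$id), ]
    ncomp <- ceiling(s$length / max_len)
    clen <- s$length / ncomp
    r_ax <- ra * clen * 4 / (pi * s$diameter^2) * 1e-2  # MOhm
    is_soma <- s$type == "soma"
    if (is_soma) {
      par0 <- 0L
      base_dist <- 0
    } else {
      psec <- s$parent_id
      if (psec == morph$soma_id) {
        # attach at the soma compartment containing the soma midpoint
        soma_first <- sec_first[as.character(morph$soma_id)]
        soma_last <- sec_last[as.character(morph$soma_id)]
        soma_len <- secs$length[secs$type == "soma"]
        nsoma <- soma_last - soma_first + 1L
        mid_comp <- soma_first + min(nsoma - 1L, floor(nsoma / 2 - 1e-9))
        par0 <- mid_comp
        base_dist <- 0
      } else {
        par0 <- sec_last[as.character(psec)]
        base_dist <- sec_root_dist[as.character(psec)] +
          secs$length[match(psec, secs$id)]
      }
    }
    for (j in seq_len(ncomp)) {
      center <- (j - 0.5) * clen
      rows[[nxt]] <- data.frame(
        index = nxt,
        parent = if (j == 1L) par0 else nxt - 1L,
        section_id = sid, pos = center, length = clen,
        diameter = s$diameter, area = pi * s$diameter * clen,
        r_axial = r_ax,
        path_dist = if (is_soma) 0 else base_dist + center,
        is_soma = is_soma, stringsAsFactors = FALSE)
      nxt <- nxt + 1L
    }
    sec_first[as.character(sid)] <- nxt - ncomp
    sec_last[as.character(sid)] <- nxt - 1L
    sec_root_dist[as.character(sid)] <- if (is_soma) 0 else base_dist
  }
  tree <- do.call(rbind, rows)
  rownames(tree) <- NULL
  attr(tree, "ra") <- ra
  attr(tree, "soma_id") <- morph$soma_id
  class(tree) <- c("fsi_comptree", "data.frame")
  tree
}

#' Map a path position to a compartment
#'
#' @param tree an `fsi_comptree`.
#' @param distance path distance from the soma-dendrite junction, um.
#' @param section_id dendritic section to search (default: first dendrite).
#' @return The compartment index whose span contains `distance`.
#' @export
site_to_compartment <- function(tree, distance, section_id = NULL) {
  dend <- tree[!tree$is_soma, ]
  if (is.null(section_id)) section_id <- min(dend$section_id)
  d <- dend[dend$section_id == section_id, ]
  if (nrow(d) == 0) stop("no such dendritic section: ", section_id)
  lo <- d$path_dist - d$length / 2
  hi <- d$path_dist + d$length / 2
  hit <- which(distance >= lo - 1e-9 & distance <= hi + 1e-9)
  if (length(hit) == 0)
    stop("position ", distance, " um is outside section ", section_id)
  d$index[hit[1]]
}

#' Morphology JSON serialization
#'
#' Writes/reads the sections table as a JSON array of section objects.
#'
#' @param morph an `fsi_morphology`.
#' @param path file path.
#' @return `path` / an `fsi_morphology`.
#' @export
write_morphology_json <- function(morph, path) {
  stopifnot(inherits(morph, "fsi_morphology"))
  jsonlite::write_json(morph$sections, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_morphology_json
#' @export
read_morphology_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$parent_id <- ifelse(is.na(df$parent_id) | is.null(df$parent_id),
                         NA_integer_, as.integer(df$parent_id))
  fsi_morphology(df)
}
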