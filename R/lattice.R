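#' Lattice geometry parameters
#'
#' Describes the fixed geometry of a simulated microtubule end: the number of
#' protofilaments, the layer registry across the seam interface, and the axial
#' rise of one alpha/beta-tubulin dimer (used to convert subunit counts to nm).
#'
#' The lattice is modelled as `n_protofilaments` gap-free columns of dimers
#' joined laterally in a ring. The 12 ordinary (B-lattice) interfaces are
#' flush in integer-layer coordinates: a subunit at layer `L` contacts the
#' neighbouring column iff that column occupies layer `L`. The single seam
#' interface is staggered by `seam_offset` layers (default 0.5, the
#' half-dimer A-lattice-like registry of the seam): a seam subunit overlaps
#' two partner layers on the other side, and each partial overlap counts as
#' a fractional lateral bond whose binding free energy adds, i.e. the site
#' KD picks up a factor `(KD_corner/KD_long)^w` for total lateral bond
#' weight `w`. The first protofilament sits `seam_offset` layers high
#' relative to the last at the plus-end; the minus-end mirrors this
#' orientation.
#'
#' @param n_protofilaments Number of protofilaments (>= 2; 13 gives the
#'   canonical wall with exactly one seam).
#' @param seam_offset Lateral registry shift at the seam interface, in
#'   subunit layers; may be fractional (0 = flush ring, 0.5 = half-dimer
#'   stagger, 1 = whole-layer stagger).
#' @param dimer_rise Axial length of one dimer along the protofilament (nm).
#' @return An object of class `lattice_params`.
#' @examples
#' lattice_params()
#' @export
lattice_params <- function(n_protofilaments = 13L, seam_offset = 0.5,
                           dimer_rise = 8) {
  n_protofilaments <- as.integer(n_protofilaments)
  seam_offset <- as.numeric(seam_offset)
  if (is.na(n_protofilaments) || n_protofilaments < 1L)
    stop("`n_protofilaments` must be a positive integer", call. = FALSE)
  if (is.na(seam_offset) || seam_offset < 0)
    stop("`seam_offset` must be non-negative", call. = FALSE)
  if (abs(seam_offset * 2 - round(seam_offset * 2)) > 1e-9)
    stop("`seam_offset` must be a multiple of 0.5 layers", call. = FALSE)
  if (!is.numeric(dimer_rise) || dimer_rise <= 0)
    stop("`dimer_rise` must be > 0", call. = FALSE)
  structure(
    list(n_protofilaments = n_protofilaments,
         seam_offset = seam_offset,
         dimer_rise = dimer_rise),
    class = "lattice_params"
  )
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf("lattice: %d protofilaments, seam offset %g layer(s), %.3g nm rise\n",
              x$n_protofilaments, x$seam_offset, x$dimer_rise))
  invisible(x)
}

# nucleotide codes used throughout: 0 = CPP (GMPCPP), 1 = GDP
NT_CPP <- 0L
NT_GDP <- 1L

nt_label <- function(code) c("CPP", "GDP")[code + 1L]

nt_code <- function(label) {
  out <- match(label, c("CPP", "GDP")) - 1L
  if (anyNA(out)) stop("nucleotide must be 'CPP' or 'GDP'", call. = FALSE)
  out
}

#' Initialize a blunt microtubule end lattice
#'
#' Builds a blunt lattice of immutable seed layers, all GMPCPP, from which a
#' simulation grows. Seed subunits never dissociate and never exchange their
#' nucleotide, mimicking a stabilized GMPCPP seed.
#'
#' @param params A [lattice_params()] object.
#' @param end `"plus"` or `"minus"`; recorded polarity, immutable afterwards.
#' @param seed_layers Number of immutable seed layers (>= 2).
#' @return An object of class `end_lattice` with per-protofilament nucleotide
#'   stacks (layers are 0-based; layer `seed_layers - 1` is the seed tip).
#' @examples
#' lat <- init_lattice(lattice_params(), "plus", seed_layers = 10)
#' lat
#' @export
init_lattice <- function(params, end = c("plus", "minus"), seed_layers = 10L) {
  stopifnot(inherits(params, "lattice_params"))
  end <- match.arg(end)
  seed_layers <- as.integer(seed_layers)
  if (is.na(seed_layers) || seed_layers < 2L)
    stop("`seed_layers` must be an integer >= 2", call. = FALSE)
  stacks <- replicate(params$n_protofilaments,
                      rep(NT_CPP, seed_layers), simplify = FALSE)
  structure(
    list(params = params, end = end, seed_layers = seed_layers,
         stacks = stacks),
    class = "end_lattice"
  )
}

#' @export
print.end_lattice <- function(x, ...) {
  h <- lattice_heights(x)
  cat(sprintf("%s-end lattice: %d protofilaments, %d seed layers\n",
              x$end, x$params$n_protofilaments, x$seed_layers))
  cat(sprintf("  heights above seed: %s (mean length %.2f nm)\n",
              paste(h - x$seed_layers, collapse = " "),
              mean_length_nm(x)))
  invisible(x)
}

#' Protofilament heights
#'
#' @param lattice An `end_lattice`.
#' @return Integer vector of total layers per protofilament (seed included).
#' @export
lattice_heights <- function(lattice) {
  vapply(lattice$stacks, length, integer(1))
}

#' Mean lattice length above the seed, in nm
#'
#' One subunit adds `dimer_rise / n_protofilaments` nm of mean length, so the
#' reported length matches what microscopy reads as the end position averaged
#' over protofilaments.
#'
#' @param lattice An `end_lattice`.
#' @return Mean protofilament length above the seed (nm).
#' @export
mean_length_nm <- function(lattice) {
  p <- lattice$params
  sum(lattice_heights(lattice) - lattice$seed_layers) *
    p$dimer_rise / p$n_protofilaments
}

# Total lateral bond weight of a (possibly prospective) subunit at 0-based
# `layer` on protofilament `pf`. Ordinary interfaces are flush: weight 1 iff
# the neighbour occupies `layer`. Across the seam the subunit's axial span
# is shifted by `seam_offset`, so it overlaps up to two partner layers; each
# overlap fraction contributes that fraction of a lateral bond. At the
# plus-end protofilament 1 sits `seam_offset` layers high relative to
# protofilament N (its partners lie lower); the minus-end mirrors the shift.
lateral_weight <- function(lattice, pf, layer) {
  p <- lattice$params
  n <- p$n_protofilaments
  if (n == 1L) return(0)  # a single protofilament has no lateral partners
  h <- lattice_heights(lattice)
  s <- p$seam_offset
  pf1_high <- lattice$end == "plus"
  w <- 0
  for (side in c(-1L, 1L)) {
    q <- ((pf - 1L + side) %% n) + 1L
    is_seam <- (pf == 1L && side == -1L) || (pf == n && side == 1L)
    if (!is_seam) {
      if (h[q] > layer) w <- w + 1
    } else {
      shift_down <- if (pf == 1L) pf1_high else !pf1_high
      z0 <- if (shift_down) layer - s else layer + s
      # span [z0, z0 + 1) overlaps integer layers floor(z0) and floor(z0)+1
      j <- floor(z0)
      frac_hi <- z0 - j
      if (frac_hi < 1e-12) {
        if (h[q] > j) w <- w + 1
      } else {
        if (h[q] > j) w <- w + (1 - frac_hi)
        if (h[q] > j + 1) w <- w + frac_hi
      }
    }
  }
  w
}

# Discrete site taxonomy: long_only (no lateral bond), corner (about one),
# bucket (about two). Fractional seam bonds are binned by rounding half up,
# so a half-supported seam site reports as a corner.
site_class_name <- function(weight) {
  c("long_only", "corner", "bucket")[pmin(floor(weight + 0.5), 2) + 1L]
}

#' Classify the next addition site on a protofilament
#'
#' Every addition is onto a protofilament tip and so always makes one
#' longitudinal contact; the class records how many lateral contacts the
#' incoming subunit would additionally make: `long_only` (none), `corner`
#' (one), or `bucket` (two).
#'
#' @param lattice An `end_lattice`.
#' @param pf Protofilament index (1-based).
#' @return `"long_only"`, `"corner"` or `"bucket"`.
#' @examples
#' lat <- init_lattice(lattice_params(), "plus")
#' classify_landing_site(lat, 1)  # blunt end: "bucket"
#' @export
classify_landing_site <- function(lattice, pf) {
  stopifnot(inherits(lattice, "end_lattice"))
  pf <- as.integer(pf)
  if (is.na(pf) || pf < 1L || pf > lattice$params$n_protofilaments)
    stop("invalid protofilament index", call. = FALSE)
  site_class_name(lateral_weight(lattice, pf, lattice_heights(lattice)[pf]))
}

#' Terminal (dissociable) subunits and their binding context
#'
#' Returns one row per protofilament whose tip lies above the seed, with the
#' site class of the occupied terminal position (its current lateral
#' contacts), the tip subunit's own exchangeable-site nucleotide, and the
#' interfacial nucleotide buried at the tip's longitudinal bond with the
#' lattice. At the plus-end the interfacial nucleotide belongs to the subunit
#' *below* the tip (its E-site faces the tip); at the minus-end the tip's own
#' E-site is the buried interfacial nucleotide.
#'
#' @param lattice An `end_lattice`.
#' @return A data frame with columns `pf`, `layer` (0-based), `site_class`,
#'   `lateral_weight` (total lateral bond weight; fractional at the seam),
#'   `self_nt`, `interfacial_nt`. Seed-only protofilaments are omitted.
#' @export
tip_sites <- function(lattice) {
  stopifnot(inherits(lattice, "end_lattice"))
  h <- lattice_heights(lattice)
  keep <- which(h > lattice$seed_layers)
  n <- length(keep)
  out <- data.frame(pf = integer(n), layer = integer(n),
                    site_class = character(n), lateral_weight = numeric(n),
                    self_nt = character(n), interfacial_nt = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_along(keep)) {
    pf <- keep[i]
    layer <- h[pf] - 1L
    stack <- lattice$stacks[[pf]]
    self <- stack[h[pf]]
    inter <- if (lattice$end == "plus") stack[h[pf] - 1L] else self
    w <- lateral_weight(lattice, pf, layer)
    out$pf[i] <- pf
    out$layer[i] <- layer
    out$site_class[i] <- site_class_name(w)
    out$lateral_weight[i] <- w
    out$self_nt[i] <- nt_label(self)
    out$interfacial_nt[i] <- nt_label(inter)
  }
  out
}

# --- in-place-style event application (returns the modified lattice) ------

lattice_associate <- function(lattice, pf, nt) {
  code <- if (is.character(nt)) nt_code(nt) else as.integer(nt)
  lattice$stacks[[pf]] <- c(lattice$stacks[[pf]], code)
  lattice
}

lattice_dissociate <- function(lattice, pf) {
  h <- length(lattice$stacks[[pf]])
  if (h <= lattice$seed_layers)
    stop("cannot dissociate a seed subunit", call. = FALSE)
  lattice$stacks[[pf]] <- lattice$stacks[[pf]][-h]
  lattice
}

lattice_exchange <- function(lattice, pf, nt) {
  h <- length(lattice$stacks[[pf]])
  if (h <= lattice$seed_layers)
    stop("cannot exchange a seed nucleotide", call. = FALSE)
  code <- if (is.character(nt)) nt_code(nt) else as.integer(nt)
  lattice$stacks[[pf]][h] <- code
  lattice
}

#' Tabulate a lattice as (pf, layer, nucleotide)
#'
#' @param x An `end_lattice`.
#' @param row.names,optional,... Passed over for S3 compatibility (unused).
#' @return Data frame with one row per subunit, `layer` 0-based.
#' @export
as.data.frame.end_lattice <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  h <- lattice_heights(x)
  data.frame(
    pf = rep(seq_along(x$stacks), h),
    layer = unlist(lapply(h, function(n) seq_len(n) - 1L)),
    nucleotide = nt_label(unlist(x$stacks)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a lattice snapshot as CSV
#'
#' Plain CSV with columns `pf`, `layer`, `nucleotide` plus a `#` metadata
#' header recording polarity and geometry, for debugging and test fixtures.
#'
#' @param lattice An `end_lattice`.
#' @param path File path.
#' @return `write_lattice_csv` returns `path` invisibly; `read_lattice_csv`
#'   returns an `end_lattice`.
#' @export
write_lattice_csv <- function(lattice, path) {
  meta <- c(
    sprintf("# end: %s", lattice$end),
    sprintf("# n_protofilaments: %d", lattice$params$n_protofilaments),
    sprintf("# seam_offset: %g", lattice$params$seam_offset),
    sprintf("# dimer_rise: %g", lattice$params$dimer_rise),
    sprintf("# seed_layers: %d", lattice$seed_layers)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(lattice), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice_csv
#' @export
read_lattice_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  params <- lattice_params(
    n_protofilaments = as.integer(meta$n_protofilaments),
    seam_offset = as.numeric(meta$seam_offset),
    dimer_rise = as.numeric(meta$dimer_rise)
  )
  lat <- init_lattice(params, meta$end,
                      seed_layers = as.integer(meta$seed_layers))
  df <- df[order(df$pf, df$layer), ]
  lat$stacks <- lapply(seq_len(params$n_protofilaments), function(p) {
    nt_code(df$nucleotide[df$pf == p])
  })
  stopifnot(all(lattice_heights(lat) >= lat$seed_layers))
  lat
}

# gap-freedom / seed integrity check used by tests and the debug engine path
validate_lattice <- function(lattice) {
  h <- lattice_heights(lattice)
  if (any(h < lattice$seed_layers))
    stop("protofilament shorter than the seed", call. = FALSE)
  seed_ok <- vapply(lattice$stacks, function(s)
    all(s[seq_len(lattice$seed_layers)] == NT_CPP), logical(1))
  if (!all(seed_ok))
    stop("seed subunit carries a non-CPP nucleotide", call. = FALSE)
  invisible(TRUE)
}
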