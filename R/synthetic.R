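# Canonical C-alpha geometry used by the generators (Angstrom / degrees):
# alpha-helix: radius 2.3, rise 1.5 per residue, 100 deg twist per residue;
# beta-strand: rise 3.3 per residue with alternating +-0.9 lateral offset.
.HELIX_RADIUS <- 2.3
.HELIX_RISE   <- 1.5
.HELIX_TWIST  <- 100 * pi / 180
.STRAND_RISE  <- 3.3
.STRAND_ZIG   <- 0.9

# run code under a temporary RNG state (substream discipline for families)
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Ideal secondary-structure C-alpha traces
#'
#' \code{makeIdealHelix} generates a canonical alpha-helix trace (radius 2.3
#' Angstrom, rise 1.5 per residue, 100 degrees per residue) with its axis
#' through \code{origin} along \code{direction}. \code{makeIdealStrand}
#' generates an extended zigzag (rise 3.3 per residue, alternating 0.9
#' lateral offset) whose midline runs from \code{origin} along
#' \code{direction}. Non-unit directions are normalized silently.
#'
#' @param nRes residue count (helix >= 4, strand >= 3).
#' @param origin 3-vector, axis/midline start.
#' @param direction 3-vector, axis/midline direction.
#' @return nRes x 3 coordinate matrix.
#' @examples
#' h <- makeIdealHelix(10)
#' range(sqrt(h[, 1]^2 + h[, 2]^2))  # all 2.3 from the z axis
#' @export
makeIdealHelix <- function(nRes, origin = c(0, 0, 0),
                           direction = c(0, 0, 1)) {
  if (nRes < 4L) usageError("helix needs >= 4 residues")
  d <- .unit(direction)
  u <- .anyPerp(d)
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  i <- seq_len(nRes) - 1L
  th <- i * .HELIX_TWIST
  t(origin + outer(d, i * .HELIX_RISE) +
      .HELIX_RADIUS * (outer(u, cos(th)) + outer(v, sin(th))))
}

#' @rdname makeIdealHelix
#' @export
makeIdealStrand <- function(nRes, origin = c(0, 0, 0),
                            direction = c(1, 0, 0)) {
  if (nRes < 3L) usageError("strand needs >= 3 residues")
  d <- .unit(direction)
  u <- .anyPerp(d)
  i <- seq_len(nRes) - 1L
  t(origin + outer(d, i * .STRAND_RISE) +
      outer(u, .STRAND_ZIG * (-1)^i))
}

# nres coil points bridging p -> q. The linker must read as coil to the
# C-alpha distance rules: every 2-residue chord involving a linker residue
# has to stay below the strand window and outside the helix windows, while
# consecutive spacing remains physical (2.8-4.2 A). Three constructions
# cover the gap range: a tight circular arc for short gaps, a symmetric
# omega excursion for mid-range gaps, and a zigzag with enough lateral
# amplitude for long gaps. Gaps needing more than ~3.8 A per step cannot be
# bridged and raise a generation error.
.bridgeArc <- function(p, q, nres, arcStep = 3.0) {
  g <- .norm2(q - p)
  steps <- nres + 1L
  L <- steps * arcStep
  al <- stats::uniroot(function(x) g * x / sin(x) - L,
                       c(1e-8, pi - 1e-8), tol = 1e-12)$root
  R <- g / (2 * sin(al))
  w <- .unit(q - p); u <- .anyPerp(w)
  ctr <- (p + q) / 2 - R * cos(al) * u
  t(sapply(seq_len(nres) / steps, function(t) {
    phi <- (2 * t - 1) * al
    ctr + R * sin(phi) * w + R * cos(phi) * u
  }))
}

.bridgeZigzag <- function(p, q, nres) {
  steps <- nres + 1L
  a <- .norm2(q - p) / steps
  e <- sqrt(max(0, 8.1 - a^2))
  e <- min(e, sqrt(max(0, (17.64 - a^2) / 4)))
  u <- .anyPerp(.unit(q - p))
  t(sapply(seq_len(nres), function(i)
    p + (i / steps) * (q - p) + (-1)^i * e * u))
}

# penalty-solved linker (canonical frame, cached by gap): consecutive steps
# stay physical, every 2-residue chord stays below the strand window, every
# 3-residue chord clear of the helix window
.bridgeCache <- new.env(parent = emptyenv())

.bridgeSolveCanonical <- function(g, nres) {
  key <- sprintf("%.3f_%d", g, nres)
  hit <- .bridgeCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- c(0, 0, 0); q <- c(g, 0, 0)
  inits <- list(
    .bridgeArc(p, q, nres, arcStep = 2.9),
    .bridgeArc(p, q, nres, arcStep = 3.3),
    # skewed out-of-plane start helps where planar arcs sit between windows
    .bridgeArc(p, q, nres, arcStep = 3.0) +
      outer((-1)^seq_len(nres), c(0, 0, 1.5)))
  x0 <- inits[[1L]]
  pen <- function(v) {
    X <- rbind(p, matrix(v, ncol = 3), q)
    m <- nrow(X); tot <- 0
    for (i in 1:(m - 1L)) {
      s <- .norm2(X[i + 1L, ] - X[i, ])
      tot <- tot + max(0, 2.87 - s)^2 + max(0, s - 3.75)^2
    }
    for (i in 1:(m - 2L)) {
      c2 <- .norm2(X[i + 2L, ] - X[i, ])
      tot <- tot + max(0, c2 - 5.45)^2
    }
    if (m >= 4L) for (i in 1:(m - 3L)) {
      c3 <- .norm2(X[i + 3L, ] - X[i, ])
      tot <- tot + min(max(0, c3 - 4.1), max(0, 6.05 - c3))^2
    }
    tot
  }
  o <- NULL
  for (x0 in inits) {
    oi <- stats::optim(as.vector(x0), pen, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    for (r in 1:3) {
      if (oi$value <= 1e-10) break
      oi <- stats::optim(oi$par, pen, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
    }
    if (is.null(o) || oi$value < o$value) o <- oi
    if (o$value <= 1e-10) break
  }
  if (o$value > 1e-6)
    generationError("cannot construct a coil linker over a %.1f A gap", g)
  out <- matrix(o$par, ncol = 3)
  .bridgeCache[[key]] <- out
  out
}

.bridgeSolve <- function(p, q, nres) {
  g <- .norm2(q - p)
  w <- .unit(q - p)
  u <- .anyPerp(w)
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  X <- .bridgeSolveCanonical(round(g, 3), nres)
  sweep(X %*% rbind(w, u, v), 2, p, "+")
}

.bridgePoints <- function(p, q, nres = 3L) {
  g <- .norm2(q - p)
  steps <- nres + 1L
  a <- g / steps
  if (a > 3.8)
    generationError("linker gap %.1f A too long for %d residues", g, nres)
  if (g < 2.0)
    generationError("linker gap %.1f A too short to bridge", g)
  if (a >= 2.15) .bridgeZigzag(p, q, nres)  # above ~2.85/step it may brush
  else .bridgeSolve(p, q, nres)             # the strand window (documented)
}

.sseTrace <- function(type, nRes, origin, direction) {
  if (type == "helix") makeIdealHelix(nRes, origin, direction)
  else makeIdealStrand(nRes, origin, direction)
}

#' Assemble a synthetic domain from an SSE recipe
#'
#' Builds ideal helix/strand traces per recipe row, joins consecutive
#' elements with 3-residue coil linkers (straight, or arced when the gap is
#' short, keeping consecutive C-alpha spacing physical), and returns the
#' domain together with its ground-truth annotation. Ground-truth labels are
#' assigned in sequence order with per-type counters (H1, H2, ... / E1,
#' E2, ...), the same convention \code{\link{annotateFamily}} uses for its
#' reference member.
#'
#' @param recipe data.frame with one row per SSE: \code{type}
#'   ("helix"/"strand"), \code{nRes}, origin \code{ox,oy,oz}, direction
#'   \code{dx,dy,dz}.
#' @param domainId CATH-style id for the result (chain letter is taken from
#'   its third-from-last character).
#' @param linkerRes residues per linker (adaptive bridging may need more
#'   after deletions; see \code{\link{makeFamily}}).
#' @return List with \code{structure} (\linkS4class{DomainStructure}) and
#'   \code{truth} (data.frame \code{label}, \code{type}, \code{startIdx},
#'   \code{endIdx}).
#' @examples
#' dom <- makeDomain(hairpinRecipe())
#' dom$truth
#' @export
makeDomain <- function(recipe, domainId = "synA01", linkerRes = 3L) {
  recipe <- as.data.frame(recipe)
  if (nrow(recipe) == 0L) generationError("empty recipe")
  traces <- lapply(seq_len(nrow(recipe)), function(i)
    .sseTrace(recipe$type[i], recipe$nRes[i],
              c(recipe$ox[i], recipe$oy[i], recipe$oz[i]),
              c(recipe$dx[i], recipe$dy[i], recipe$dz[i])))
  # SSEs must not clash in space
  if (length(traces) > 1L) for (i in 1:(length(traces) - 1L))
    for (j in (i + 1L):length(traces)) {
      dmin <- min(sqrt(outer(rowSums(traces[[i]]^2), rowSums(traces[[j]]^2),
                             "+") - 2 * tcrossprod(traces[[i]], traces[[j]])))
      if (is.finite(dmin) && dmin < 3.0)
        generationError("recipe SSEs %d and %d clash (min distance %.1f A)",
                        i, j, dmin)
    }
  coords <- traces[[1L]]
  counters <- c(helix = 0L, strand = 0L)
  truth <- data.frame(label = character(), type = character(),
                      startIdx = integer(), endIdx = integer(),
                      stringsAsFactors = FALSE)
  addTruth <- function(type, a, b) {
    counters[[type]] <<- counters[[type]] + 1L
    lab <- paste0(if (type == "helix") "H" else "E", counters[[type]])
    truth[nrow(truth) + 1L, ] <<- list(lab, type, a, b)
  }
  addTruth(recipe$type[1L], 1L, nrow(coords))
  if (nrow(recipe) > 1L) for (i in 2:nrow(recipe)) {
    link <- .bridgePoints(coords[nrow(coords), ], traces[[i]][1L, ],
                          linkerRes)
    coords <- rbind(coords, link)
    a <- nrow(coords) + 1L
    coords <- rbind(coords, traces[[i]])
    addTruth(recipe$type[i], a, nrow(coords))
  }
  n <- nrow(coords)
  chain <- substr(domainId, nchar(domainId) - 2L, nchar(domainId) - 2L)
  structure <- DomainStructure(domainId,
                               substr(domainId, 1L, nchar(domainId) - 3L),
                               rep(chain, n), seq_len(n), rep("", n), coords)
  list(structure = structure, truth = truth)
}

#' Specification of a synthetic perturbed family
#'
#' @param recipe base-domain recipe (see \code{\link{makeDomain}}).
#' @param nMembers number of members (>= 1).
#' @param jitterSigma per-coordinate Gaussian noise sd, Angstrom.
#' @param deletionProb independent deletion probability per SSE per member
#'   (in [0, 1)); the first member always keeps every SSE so the family
#'   retains a full-coverage reference.
#' @param seed integer seed; each member uses a substream derived from it, so
#'   removing one member does not shift the others' noise.
#' @param familyId family identifier.
#' @return A \code{familySpec} list.
#' @export
familySpec <- function(recipe, nMembers = 10L, jitterSigma = 0.3,
                       deletionProb = 0, seed = 1L,
                       familyId = "9.10.10.10") {
  if (nMembers < 1L) usageError("nMembers must be >= 1")
  if (jitterSigma < 0) usageError("jitterSigma must be >= 0")
  if (deletionProb < 0 || deletionProb >= 1)
    usageError("deletionProb must lie in [0, 1)")
  list(recipe = as.data.frame(recipe), nMembers = as.integer(nMembers),
       jitterSigma = jitterSigma, deletionProb = deletionProb,
       seed = as.integer(seed), familyId = familyId)
}

#' Generate a perturbed synthetic family with ground truth
#'
#' Produces \code{nMembers} copies of the base domain. Per member, each SSE
#' is independently deleted with probability \code{deletionProb} (linkers are
#' re-bridged with an adaptive residue count so spacing stays physical), and
#' every coordinate is jittered by i.i.d. Gaussian noise of sd
#' \code{jitterSigma}. Fully reproducible from \code{spec$seed}; member
#' substreams are independent. Member ids are "syn" + chain letter + 2-digit
#' index ("synA01", "synB02", ...).
#'
#' @param spec a \code{\link{familySpec}}.
#' @return List with \code{familyId} and \code{members}: a named list of
#'   \code{list(structure, truth)} as in \code{\link{makeDomain}}; the truth
#'   labels of a member with deletions are the subset kept from the base
#'   domain.
#' @examples
#' fam <- makeFamily(familySpec(hairpinRecipe(), nMembers = 3,
#'                              jitterSigma = 0, seed = 7))
#' names(fam$members)
#' @export
makeFamily <- function(spec) {
  base <- spec$recipe
  members <- list()
  chains <- LETTERS[(seq_len(spec$nMembers) - 1L) %% 26L + 1L]
  for (m in seq_len(spec$nMembers)) {
    id <- sprintf("syn%s%02d", chains[m], m)
    sub <- spec$seed * 1009L + m * 7919L
    members[[id]] <- .withSeed(sub, {
      keep <- rep(TRUE, nrow(base))
      if (spec$deletionProb > 0 && m > 1L)
        keep <- stats::runif(nrow(base)) >= spec$deletionProb
      if (!any(keep)) keep[1L] <- TRUE
      rec <- base[keep, , drop = FALSE]
      dom <- .makeDomainAdaptive(rec, id)
      # ground-truth labels follow the base domain's sequence-order naming
      baseTruth <- makeDomain(base, "synZ99")$truth
      dom$truth$label <- baseTruth$label[keep]
      dom$truth$type <- baseTruth$type[keep]
      if (spec$jitterSigma > 0) {
        xyz <- dom$structure@coords
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitterSigma),
                            ncol = 3)
        dom$structure@coords <- xyz
      }
      dom
    })
  }
  list(familyId = spec$familyId, members = members)
}

# like makeDomain but picks a linker residue count per junction so that
# re-bridged deletions stay physical
.makeDomainAdaptive <- function(recipe, domainId) {
  recipe <- as.data.frame(recipe)
  if (nrow(recipe) <= 1L) return(makeDomain(recipe, domainId))
  traces <- lapply(seq_len(nrow(recipe)), function(i)
    .sseTrace(recipe$type[i], recipe$nRes[i],
              c(recipe$ox[i], recipe$oy[i], recipe$oz[i]),
              c(recipe$dx[i], recipe$dy[i], recipe$dz[i])))
  coords <- traces[[1L]]
  truth <- data.frame(label = NA_character_, type = recipe$type[1L],
                      startIdx = 1L, endIdx = nrow(coords),
                      stringsAsFactors = FALSE)
  for (i in 2:nrow(recipe)) {
    g <- .norm2(traces[[i]][1L, ] - coords[nrow(coords), ])
    steps <- as.integer(ceiling(g / 2.6))
    if (steps > 4L && g / steps < 2.14) steps <- steps - 1L
    nres <- max(3L, steps - 1L)
    link <- .bridgePoints(coords[nrow(coords), ], traces[[i]][1L, ], nres)
    coords <- rbind(coords, link)
    a <- nrow(coords) + 1L
    coords <- rbind(coords, traces[[i]])
    truth[nrow(truth) + 1L, ] <- list(NA_character_, recipe$type[i], a,
                                      nrow(coords))
  }
  n <- nrow(coords)
  chain <- substr(domainId, nchar(domainId) - 2L, nchar(domainId) - 2L)
  list(structure = DomainStructure(domainId,
                                   substr(domainId, 1L, nchar(domainId) - 3L),
                                   rep(chain, n), seq_len(n), rep("", n),
                                   coords),
       truth = truth)
}

#' Stock recipes for synthetic fixtures
#'
#' \code{hairpinRecipe}: two antiparallel strands 4.8 Angstrom apart.
#' \code{meanderRecipe}: k antiparallel strands in a flat meander sheet.
#' \code{barrelRecipe}: strands arranged on a closed ring (a beta-barrel),
#' which the sheet builder rejects by design. \code{mixedRecipe}: two
#' helices plus a hairpin, a small alpha/beta domain.
#'
#' @param nRes residues per strand.
#' @param spacing inter-strand spacing, Angstrom.
#' @param k number of strands.
#' @return A recipe data.frame for \code{\link{makeDomain}}.
#' @export
hairpinRecipe <- function(nRes = 5L, spacing = 4.8) {
  len <- (nRes - 1L) * .STRAND_RISE
  data.frame(type = "strand", nRes = nRes,
             ox = c(0, spacing), oy = c(0, len), oz = 0,
             dx = 0, dy = c(1, -1), dz = 0)
}

#' @rdname hairpinRecipe
#' @export
meanderRecipe <- function(k = 3L, nRes = 5L, spacing = 4.8) {
  len <- (nRes - 1L) * .STRAND_RISE
  i <- seq_len(k) - 1L
  up <- i %% 2L == 0L
  data.frame(type = "strand", nRes = nRes,
             ox = i * spacing, oy = ifelse(up, 0, len), oz = 0,
             dx = 0, dy = ifelse(up, 1, -1), dz = 0)
}

#' @rdname hairpinRecipe
#' @export
barrelRecipe <- function(k = 6L, nRes = 5L, radius = NULL) {
  if (k < 3L) usageError("a barrel needs >= 3 strands")
  if (is.null(radius)) radius <- 4.8 / (2 * sin(pi / k))
  len <- (nRes - 1L) * .STRAND_RISE
  th <- 2 * pi * (seq_len(k) - 1L) / k
  up <- seq_len(k) %% 2L == 1L
  data.frame(type = "strand", nRes = nRes,
             ox = radius * cos(th), oy = ifelse(up, 0, len),
             oz = radius * sin(th),
             dx = 0, dy = ifelse(up, 1, -1), dz = 0)
}

#' @rdname hairpinRecipe
#' @export
mixedRecipe <- function() {
  data.frame(
    type = c("helix", "helix", "strand", "strand"),
    nRes = c(12L, 10L, 5L, 5L),
    ox = c(0, 8, 17.5, 22.3), oy = c(0, 13, 0, 13.2), oz = c(0, -1, 0, 0),
    dx = c(0, 0, 0, 0), dy = c(1, -1, 1, -1), dz = c(0, 0, 0, 0))
}

#' Random compact synthetic domain recipe
#'
#' Draws a chain of \code{nSSE} elements (helix or strand, equal odds) with
#' random lengths, placed sequentially so consecutive elements are linkable
#' (gap 6-13 Angstrom) and no two elements clash, emulating the packing
#' density of a small globular domain.
#'
#' @param nSSE number of elements.
#' @param seed integer seed.
#' @return A recipe data.frame.
#' @export
randomDomainRecipe <- function(nSSE, seed) {
  .withSeed(seed, {
    rec <- NULL
    endPt <- c(0, 0, 0)
    traces <- list()
    for (i in seq_len(nSSE)) {
      type <- if (stats::runif(1) < 0.5) "helix" else "strand"
      nRes <- if (type == "helix") sample(7:14, 1) else sample(5:8, 1)
      for (try in 1:500) {
        dir <- .unit(stats::rnorm(3))
        if (i == 1L) { org <- c(0, 0, 0) }
        else {
          gdir <- .unit(stats::rnorm(3))
          # aim for the short-turn or medium-loop bridging regimes
          gap <- if (stats::runif(1) < 0.4) stats::runif(1, 4.5, 6.8)
                 else stats::runif(1, 9.0, 10.4)
          org <- endPt + gap * gdir
        }
        tr <- .sseTrace(type, nRes, org, dir)
        ok <- TRUE
        if (i > 1L) {
          # gap measured trace end to trace start (offsets included)
          gTrue <- .norm2(tr[1L, ] - endPt)
          ok <- (gTrue >= 3.0 && gTrue <= 6.8) ||
                (gTrue >= 8.9 && gTrue <= 10.4)
        }
        if (ok) for (pt in traces) {
          d2m <- outer(rowSums(tr^2), rowSums(pt^2), "+") -
            2 * tcrossprod(tr, pt)
          dmin <- sqrt(max(0, min(d2m)))
          if (!is.finite(dmin) || dmin < 4.0) { ok <- FALSE; break }
        }
        if (ok) break
      }
      traces[[i]] <- tr
      endPt <- tr[nRes, ]
      rec <- rbind(rec, data.frame(type = type, nRes = nRes,
                                   ox = org[1], oy = org[2], oz = org[3],
                                   dx = dir[1], dy = dir[2], dz = dir[3]))
    }
    rec
  })
}

#' Write a synthetic family to disk as minimal PDB files
#'
#' Emits one minimal PDB per member, a CATH-style ranges TSV
#' (\code{domain_id<TAB>path<TAB>chain<TAB>start<TAB>end}) and a ground-truth
#' JSON, for end-to-end command-line tests.
#'
#' @param family result of \code{\link{makeFamily}}.
#' @param dir output directory (created if needed).
#' @return Path of the ranges TSV, invisibly.
#' @export
writeFamilyFixture <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- character()
  truth <- list()
  for (id in names(family$members)) {
    mem <- family$members[[id]]
    p <- file.path(dir, paste0(id, ".pdb"))
    writeMinimalPDB(mem$structure, p)
    rows <- c(rows, paste(id, p, mem$structure@resChain[1L],
                          min(mem$structure@resSeq),
                          max(mem$structure@resSeq), sep = "\t"))
    truth[[id]] <- mem$truth
  }
  rangesPath <- file.path(dir, "ranges.tsv")
  writeLines(rows, rangesPath)
  jsonlite::write_json(
    list(family = family$familyId, truth = truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(rangesPath)
}
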