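#' Standard H-DAB stain matrix
#'
#' Columns are unit optical-density vectors (R, G, B) for haematoxylin, DAB
#' and a residual channel (their normalised cross product), after
#' Ruifrok-Johnston colour deconvolution practice.
#'
#' @param hematoxylin,dab length-3 stain vectors (normalised internally).
#' @return a 3x3 matrix with columns `hematoxylin`, `dab`, `residual`.
#' @export
hdab_stain_matrix <- function(hematoxylin = c(0.65, 0.70, 0.29),
                              dab = c(0.27, 0.57, 0.78)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6) stopf("stain vectors are collinear")
  m <- cbind(hematoxylin = h, dab = d, residual = r / nr)
  rownames(m) <- c("R", "G", "B")
  m
}

#' Specify a synthetic TMA core image
#'
#' Samples a nucleus layout for one core: epithelial nuclei in glandular
#' clusters, elongated stromal nuclei and small round lymphocytes scattered
#' between them, with optional artifacts (a strongly DAB-stained fold band,
#' weakly stained background blobs).  Placement uses seeded dart throwing
#' with a minimum separation, so layouts are reproducible.
#'
#' @param diameter core diameter in pixels.
#' @param n_epithelial,n_stromal,n_lymphocyte nucleus counts per class.
#' @param frac_pos_epithelial,frac_pos_stromal fractions of epithelial and
#'   stromal nuclei that are DAB positive.
#' @param frac_pos_lymphocyte fraction of lymphocytes rendered DAB positive
#'   (lymphocytes retain MMR expression; their class ignores positivity).
#' @param n_clusters number of glandular clusters.
#' @param fold add a fold artifact band (strong background)?
#' @param n_weak_blobs number of weakly stained background blobs.
#' @param dab_od_positive mean DAB optical density of positive nuclei.
#' @param background_od optical density of the tissue background wash.
#' @param seed RNG seed.
#' @return object of class `core_spec`: `diameter`, `nuclei` (data frame
#'   `id, x, y, a, b, theta, class, hema_od, dab_od`), `artifacts` (list),
#'   `background_od`, `seed`.
#' @export
simulate_core_spec <- function(diameter = 320,
                               n_epithelial = 300,
                               n_stromal = 70,
                               n_lymphocyte = 45,
                               frac_pos_epithelial = 0.8,
                               frac_pos_stromal = 0.85,
                               frac_pos_lymphocyte = 0.9,
                               n_clusters = 6,
                               fold = FALSE,
                               n_weak_blobs = 0,
                               dab_od_positive = 0.65,
                               background_od = 0.06,
                               seed = 1L) {
  with_seed(substream_seed(seed, 1), {
    R <- diameter / 2
    cx <- cy <- R + 0.5
    in_disc <- function(x, y, margin) (x - cx)^2 + (y - cy)^2 <= (R - margin)^2

    # grid-hash dart throwing: accepted nuclei are indexed by coarse grid
    # cell so each candidate only checks its 3x3 neighbourhood
    cell <- 16
    ncell <- ceiling(diameter / cell)
    grid <- new.env(parent = emptyenv())
    px <- py <- pr <- numeric(0)
    key <- function(cx, cy) paste0(cx, ",", cy)
    accept <- function(x, y, r) {
      cx <- floor(x / cell); cy <- floor(y / cell)
      for (dx in -1:1) for (dy in -1:1) {
        ids <- grid[[key(cx + dx, cy + dy)]]
        if (!is.null(ids)) {
          d2 <- (px[ids] - x)^2 + (py[ids] - y)^2
          if (any(d2 < (0.8 * (pr[ids] + r))^2)) return(FALSE)
        }
      }
      i <- length(px) + 1L
      px[i] <<- x; py[i] <<- y; pr[i] <<- r
      k <- key(cx, cy)
      grid[[k]] <- c(grid[[k]], i)
      TRUE
    }
    place <- function(n, propose, maxax) {
      out <- matrix(NA_real_, n, 2)
      got <- 0L; tries <- 0L
      while (got < n && tries < n * 60L) {
        tries <- tries + 1L
        p <- propose()
        if (!in_disc(p[1], p[2], maxax + 1)) next
        if (!accept(p[1], p[2], maxax)) next
        got <- got + 1L
        out[got, ] <- p
      }
      out[seq_len(got), , drop = FALSE]
    }
    # glandular cluster centres
    ctr <- matrix(NA_real_, n_clusters, 2)
    for (k in seq_len(n_clusters)) {
      repeat {
        p <- c(runif(1, R * 0.25, 2 * R - R * 0.25),
               runif(1, R * 0.25, 2 * R - R * 0.25))
        if (in_disc(p[1], p[2], R * 0.2)) break
      }
      ctr[k, ] <- p
    }
    cluster_sd <- R * 0.22

    nuclei <- list()
    nid <- 0L
    add <- function(xy, a, b, theta, cls, hema, dab) {
      n <- nrow(xy)
      if (n == 0) return(NULL)
      ids <- nid + seq_len(n)
      nid <<- nid + n
      data.frame(id = ids, x = xy[, 1], y = xy[, 2], a = a, b = b,
                 theta = theta, class = cls, hema_od = hema, dab_od = dab,
                 stringsAsFactors = FALSE)
    }

    # epithelial: clustered, roughly round, medium size
    prop_epi <- function()
      ctr[sample.int(n_clusters, 1), ] + rnorm(2, 0, cluster_sd)
    pe <- place(n_epithelial, prop_epi, maxax = 7)
    ne <- nrow(pe)
    pos_e <- runif(ne) < frac_pos_epithelial
    epi <- add(pe,
               a = runif(ne, 5.5, 7), b = runif(ne, 4.3, 5.4),
               theta = runif(ne, 0, pi),
               cls = ifelse(pos_e, "pos_tumor", "neg_tumor"),
               hema = pmin(pmax(rnorm(ne, 0.75, 0.07), 0.5), 1),
               dab = ifelse(pos_e,
                            pmax(rnorm(ne, dab_od_positive, 0.05), 0.01),
                            0.02))

    # stromal: scattered, thin and elongated (eccentricity > 0.85)
    prop_sc <- function() c(runif(1, 2, 2 * R - 2), runif(1, 2, 2 * R - 2))
    ps <- place(n_stromal, prop_sc, maxax = 11)
    ns <- nrow(ps)
    pos_s <- runif(ns) < frac_pos_stromal
    str_ <- add(ps,
                a = runif(ns, 8.5, 11), b = runif(ns, 1.6, 2.3),
                theta = runif(ns, 0, pi),
                cls = ifelse(pos_s, "pos_stroma", "neg_stroma"),
                hema = pmin(pmax(rnorm(ns, 0.7, 0.07), 0.5), 1),
                dab = ifelse(pos_s,
                             pmin(pmax(rnorm(ns, 0.5, 0.08), 0.3), 0.9),
                             0.02))

    # lymphocytes: small, dense, round (area < half the epithelial median)
    pl <- place(n_lymphocyte, prop_sc, maxax = 3)
    nl <- nrow(pl)
    pos_l <- runif(nl) < frac_pos_lymphocyte
    rad <- runif(nl, 2.2, 3.0)
    lym <- add(pl, a = rad, b = rad * runif(nl, 0.9, 1),
               theta = runif(nl, 0, pi), cls = "lymphocyte",
               hema = pmin(pmax(rnorm(nl, 0.95, 0.05), 0.7), 1.1),
               dab = ifelse(pos_l, 0.5, 0.02))

    artifacts <- list()
    if (isTRUE(fold)) {
      theta_f <- runif(1, 0, pi)
      artifacts[[length(artifacts) + 1]] <-
        list(type = "fold", x = cx + runif(1, -R / 3, R / 3),
             y = cy + runif(1, -R / 3, R / 3),
             theta = theta_f, width = diameter * 0.11,
             length = diameter * 1.2, dab_od = 1.3, hema_od = 0.3)
    }
    if (n_weak_blobs > 0) {
      for (b in seq_len(n_weak_blobs)) {
        repeat {
          p <- c(runif(1, 0, 2 * R), runif(1, 0, 2 * R))
          if (in_disc(p[1], p[2], 16)) break
        }
        artifacts[[length(artifacts) + 1]] <-
          list(type = "blob", x = p[1], y = p[2], r = runif(1, 8, 14),
               dab_od = 0.1, hema_od = 0.04)
      }
    }

    spec <- list(diameter = as.integer(diameter),
                 nuclei = do.call(rbind, Filter(Negate(is.null),
                                                list(epi, str_, lym))),
                 artifacts = artifacts,
                 background_od = background_od,
                 seed = as.integer(seed))
    class(spec) <- "core_spec"
    spec
  })
}

#' Render a core specification to a brightfield H-DAB image
#'
#' Forward Beer-Lambert synthesis: per-pixel optical densities of
#' haematoxylin and DAB are accumulated from the background wash, nuclei and
#' artifacts, then transmitted through the stain vectors as
#' `I = 255 * 10^-(OD_h * h + OD_d * d)` per RGB channel.  Deterministic
#' given the spec (and its seed, used for background texture).
#'
#' @param spec a `core_spec` (from [simulate_core_spec()] or hand-built with
#'   the same fields).
#' @param stains stain matrix from [hdab_stain_matrix()].
#' @param max_packing maximum allowed ratio of summed nucleus area to core
#'   disc area; denser specs are rejected as unrenderable.
#' @return object of class `rendered_core`: `rgb` (integer array
#'   width x height x 3 in 0..255), `mask` (integer label matrix, nucleus and
#'   artifact ids), `truth` (data frame per object: `id, x, y, class,
#'   positive`), `spec`.
#' @export
render_core <- function(spec, stains = hdab_stain_matrix(),
                        max_packing = 0.55) {
  stopifnot(inherits(spec, "core_spec") ||
              all(c("diameter", "nuclei", "background_od") %in% names(spec)))
  d <- spec$diameter
  nuc <- spec$nuclei
  R <- d / 2
  if (!is.null(nuc) && nrow(nuc) > 0) {
    packing <- sum(pi * nuc$a * nuc$b) / (pi * R^2)
    if (packing > max_packing)
      stopf("nucleus packing fraction %.2f exceeds limit %.2f",
            packing, max_packing)
  }

  xs <- matrix(rep(seq_len(d), d), d, d)
  ys <- matrix(rep(seq_len(d), each = d), d, d)
  disc <- (xs - R - 0.5)^2 + (ys - R - 0.5)^2 <= R^2

  od_h <- matrix(0, d, d)
  od_d <- matrix(0, d, d)
  wash <- spec$background_od %||% 0
  od_h[disc] <- od_h[disc] + wash * 0.7
  od_d[disc] <- od_d[disc] + wash * 0.3
  # faint seeded texture so tissue background is not perfectly flat
  if (wash > 0)
    od_h[disc] <- od_h[disc] + with_seed(substream_seed(spec$seed %||% 0L, 2),
                                         abs(rnorm(sum(disc), 0, 0.15 * wash)))

  mask <- matrix(0L, d, d)
  truth <- NULL

  fill_ellipse <- function(x0, y0, a, b, theta, id, hema, dab) {
    r <- max(a, b)
    xr <- max(1L, floor(x0 - r)):min(d, ceiling(x0 + r))
    yr <- max(1L, floor(y0 - r)):min(d, ceiling(y0 + r))
    gx <- outer(xr, rep(1, length(yr))) - x0
    gy <- outer(rep(1, length(xr)), yr) - y0
    ct <- cos(theta); st <- sin(theta)
    u <- (gx * ct + gy * st) / a
    v <- (-gx * st + gy * ct) / b
    inside <- u^2 + v^2 <= 1
    ix <- xr[row(inside)[inside]]
    iy <- yr[col(inside)[inside]]
    lin <- cbind(ix, iy)
    od_h[lin] <<- od_h[lin] + hema
    od_d[lin] <<- od_d[lin] + dab
    if (id > 0) mask[lin] <<- id
  }

  if (!is.null(nuc) && nrow(nuc) > 0) {
    for (i in seq_len(nrow(nuc)))
      fill_ellipse(nuc$x[i], nuc$y[i], nuc$a[i], nuc$b[i], nuc$theta[i],
                   nuc$id[i], nuc$hema_od[i], nuc$dab_od[i])
    truth <- data.frame(id = nuc$id, x = nuc$x, y = nuc$y, class = nuc$class,
                        positive = ifelse(nuc$class %in%
                                            c("pos_tumor", "pos_stroma"), TRUE,
                                          ifelse(nuc$class %in%
                                                   c("neg_tumor", "neg_stroma"),
                                                 FALSE, NA)),
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        class = character(0), positive = logical(0))
  }

  next_id <- if (nrow(truth) > 0) max(truth$id) else 0L
  for (art in spec$artifacts %||% list()) {
    next_id <- next_id + 1L
    if (art$type == "fold") {
      ct <- cos(art$theta); st <- sin(art$theta)
      u <- (xs - art$x) * ct + (ys - art$y) * st
      v <- -(xs - art$x) * st + (ys - art$y) * ct
      band <- abs(v) <= art$width / 2 & abs(u) <= art$length / 2 & disc
      od_d[band] <- od_d[band] + art$dab_od
      od_h[band] <- od_h[band] + art$hema_od
      mask[band] <- next_id
      truth <- rbind(truth, data.frame(id = next_id, x = art$x, y = art$y,
                                       class = "strong_bg", positive = NA,
                                       stringsAsFactors = FALSE))
    } else if (art$type == "blob") {
      fill_ellipse(art$x, art$y, art$r, art$r, 0, next_id,
                   art$hema_od, art$dab_od)
      truth <- rbind(truth, data.frame(id = next_id, x = art$x, y = art$y,
                                       class = "weak_bg", positive = NA,
                                       stringsAsFactors = FALSE))
    } else stopf("unknown artifact type '%s'", art$type)
  }

  m <- stains
  trans <- function(ch) {
    pmax(pmin(as.integer(round(
      255 * 10^-(od_h * m[ch, "hematoxylin"] + od_d * m[ch, "dab"]))), 255L), 0L)
  }
  rgb <- array(0L, c(d, d, 3))
  rgb[, , 1] <- trans("R"); rgb[, , 2] <- trans("G"); rgb[, , 3] <- trans("B")

  structure(list(rgb = rgb, mask = mask, truth = truth, spec = spec),
            class = "rendered_core")
}

#' Colour deconvolution of an H-DAB RGB image into stain optical densities
#'
#' `OD = -log10(I / 255)` per channel, unmixed by the inverse of the stain
#' matrix; rendering then deconvolving recovers the input densities to
#' within 8-bit quantisation (< 0.02 OD).
#'
#' @param rgb integer/numeric array width x height x 3 with values 0..255.
#' @param stains stain matrix from [hdab_stain_matrix()].
#' @return numeric array width x height x 3: haematoxylin, DAB and residual
#'   optical-density channels.
#' @export
deconvolve_stains <- function(rgb, stains = hdab_stain_matrix()) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stopf("input must be a width x height x 3 RGB array")
  if (abs(det(stains)) < 1e-6) stopf("singular stain matrix")
  d1 <- dim(rgb)[1]; d2 <- dim(rgb)[2]
  od <- -log10(pmax(rgb, 1) / 255)
  flat <- matrix(od, ncol = 3)
  conc <- flat %*% t(solve(stains))
  array(conc, c(d1, d2, 3))
}

#' Parameters of the classical cell caller
#'
#' Defaults are calibrated against [render_core()] defaults, not against any
#' scanner or commercial pipeline.
#'
#' @param detect_threshold total (haematoxylin + DAB) OD above which a pixel
#'   is candidate tissue object after smoothing.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_area minimum object area (px^2); smaller components are debris
#'   and are discarded.
#' @param positivity_od mean nuclear DAB OD at or above which a tumour or
#'   stromal cell is called positive (midway between the rendered negative
#'   (~0) and positive (>= 0.4) modes).
#' @param lymph_area_max,lymph_ecc_max area/eccentricity bounds for the
#'   lymphocyte call.
#' @param stromal_ecc_min eccentricity above which a nucleus is stromal.
#' @param hema_min minimum mean haematoxylin OD for a component to be a
#'   nucleus at all; fainter components are background objects.
#' @param strong_bg_od mean DAB OD separating strong from weak background.
#' @param fold_od,fold_min_area per-pixel DAB OD and component area defining
#'   a fold band (excluded from nucleus detection, counted as strong
#'   background).
#' @param watershed_tolerance,watershed_ext passed to [EBImage::watershed()].
#' @export
cell_caller_params <- function(detect_threshold = 0.3,
                               smooth_sigma = 1.2,
                               min_area = 12,
                               positivity_od = 0.15,
                               lymph_area_max = 45,
                               lymph_ecc_max = 0.8,
                               stromal_ecc_min = 0.88,
                               hema_min = 0.2,
                               strong_bg_od = 0.45,
                               fold_od = 0.95,
                               fold_min_area = 600,
                               watershed_tolerance = 1,
                               watershed_ext = 1) {
  as.list(environment())
}

#' Detect, segment and classify cells in a rendered core
#'
#' The classical stand-in for a learned single-cell classifier:
#' colour deconvolution, fold-band exclusion, Gaussian smoothing,
#' thresholding of total stain OD, connected components, distance-transform
#' watershed splitting of touching nuclei, then per-object class assignment
#' from area, eccentricity and mean stain densities, and DAB positivity for
#' tumour and stromal cells.
#'
#' @param rendered a `rendered_core` (or any list with an `rgb` array).
#' @param params list from [cell_caller_params()].
#' @param stains stain matrix.
#' @return list of class `cell_calls`: `calls` (data frame `id, x, y, area,
#'   eccentricity, mean_dab, mean_hema, class, positive`), `counts` (named
#'   vector over the seven classes), `n_objects`.
#' @export
call_cells <- function(rendered, params = cell_caller_params(),
                       stains = hdab_stain_matrix()) {
  rgb <- if (is.list(rendered)) rendered$rgb else rendered
  if (is.null(dim(rgb)) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stopf("input image must be a width x height x 3 RGB array")
  od <- deconvolve_stains(rgb, stains)
  h <- od[, , 1]; dab <- od[, , 2]

  # fold bands: contiguous strongly DAB-stained regions, excluded from
  # nucleus detection and counted as strong background
  fold_px <- dab > params$fold_od
  fold_calls <- NULL
  fold_mask <- matrix(FALSE, nrow(h), ncol(h))
  if (any(fold_px)) {
    flab <- EBImage::bwlabel(fold_px)
    fareas <- tabulate(flab[flab > 0])
    big <- which(fareas >= params$fold_min_area)
    if (length(big) > 0) {
      fold_mask <- matrix(flab %in% big, nrow(h), ncol(h))
      fold_calls <- do.call(rbind, lapply(big, function(k) {
        idx <- which(flab == k, arr.ind = TRUE)
        data.frame(id = NA_integer_, x = mean(idx[, 1]), y = mean(idx[, 2]),
                   area = fareas[k], eccentricity = NA_real_,
                   mean_dab = mean(dab[flab == k]),
                   mean_hema = mean(h[flab == k]),
                   class = "strong_bg", positive = NA,
                   stringsAsFactors = FALSE)
      }))
    }
  }

  total <- h + pmax(dab, 0)
  total[fold_mask] <- 0
  sm <- as.matrix(EBImage::gblur(total, sigma = params$smooth_sigma))
  bin <- sm > params$detect_threshold
  calls <- NULL
  if (any(bin)) {
    dm <- EBImage::distmap(bin)
    w <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = params$watershed_ext)
    w <- as.matrix(w)
    nlab <- max(w)
    if (nlab > 0) {
      idx <- which(w > 0)
      lab <- w[idx]
      area <- tabulate(lab, nlab)
      sum_d <- sum_h <- rep(0, nlab)
      rs_d <- rowsum(dab[idx], lab)
      rs_h <- rowsum(h[idx], lab)
      sum_d[as.integer(rownames(rs_d))] <- rs_d[, 1]
      sum_h[as.integer(rownames(rs_h))] <- rs_h[, 1]
      mom <- EBImage::computeFeatures.moment(w)
      if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                           dimnames = list(NULL, names(mom)))
      keep <- which(area >= params$min_area)
      if (length(keep) > 0) {
        mean_d <- sum_d[keep] / area[keep]
        mean_h <- sum_h[keep] / area[keep]
        ecc <- mom[keep, "m.eccentricity"]
        a <- area[keep]
        cls <- ifelse(mean_h < params$hema_min,
                      ifelse(mean_d >= params$strong_bg_od, "strong_bg",
                             "weak_bg"),
                      ifelse(a <= params$lymph_area_max &
                               ecc <= params$lymph_ecc_max, "lymphocyte",
                             ifelse(ecc >= params$stromal_ecc_min,
                                    ifelse(mean_d >= params$positivity_od,
                                           "pos_stroma", "neg_stroma"),
                                    ifelse(mean_d >= params$positivity_od,
                                           "pos_tumor", "neg_tumor"))))
        pos <- ifelse(cls %in% c("pos_tumor", "pos_stroma"), TRUE,
                      ifelse(cls %in% c("neg_tumor", "neg_stroma"), FALSE, NA))
        calls <- data.frame(id = keep, x = mom[keep, "m.cx"],
                            y = mom[keep, "m.cy"], area = a,
                            eccentricity = ecc, mean_dab = mean_d,
                            mean_hema = mean_h, class = cls, positive = pos,
                            stringsAsFactors = FALSE)
      }
    }
  }
  calls <- rbind(calls, fold_calls)
  if (is.null(calls))
    calls <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        area = numeric(0), eccentricity = numeric(0),
                        mean_dab = numeric(0), mean_hema = numeric(0),
                        class = character(0), positive = logical(0))
  counts <- vapply(CELL_CLASSES, function(cl) sum(calls$class == cl),
                   integer(1))
  structure(list(calls = calls, counts = counts, n_objects = nrow(calls)),
            class = "cell_calls")
}

#' Aggregate cell calls (or rendered truth) into a cell-count-table row
#'
#' @param counts named class-count vector (e.g. `call_cells()$counts`), or a
#'   `cell_calls` / `rendered_core` object.
#' @param case_id,core_id,region,protein row metadata.
#' @return one-row data frame in the [generate_cohort()] `cells` format.
#' @export
counts_to_row <- function(counts, case_id, core_id, region, protein) {
  if (inherits(counts, "cell_calls")) counts <- counts$counts
  if (inherits(counts, "rendered_core")) {
    tab <- table(factor(counts$truth$class, CELL_CLASSES))
    counts <- setNames(as.integer(tab), CELL_CLASSES)
  }
  row <- data.frame(case_id = case_id, core_id = core_id, region = region,
                    protein = protein, stringsAsFactors = FALSE)
  for (cl in CELL_CLASSES) row[[cl]] <- as.integer(counts[[cl]] %||% 0L)
  row$stain_fail <- FALSE
  row
}

#' Match calls to rendered ground truth and measure class accuracy
#'
#' Each call is matched to the truth object whose mask id lies under (or
#' nearest within a 5x5 window of) its centroid.
#'
#' @param rendered a `rendered_core`.
#' @param cells a `cell_calls` result for that core.
#' @return list: `matched` (data frame `call_class, truth_class`), `accuracy`
#'   (fraction of matched calls with the correct 7-way class), `n_unmatched`.
#' @export
match_calls <- function(rendered, cells) {
  calls <- cells$calls
  d <- dim(rendered$mask)
  truth_of <- function(x, y) {
    xi <- round(x); yi <- round(y)
    win <- 2L
    xs <- max(1, xi - win):min(d[1], xi + win)
    ys <- max(1, yi - win):min(d[2], yi + win)
    ids <- rendered$mask[xs, ys]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(NA_integer_)
    as.integer(names(sort(table(ids), decreasing = TRUE))[1])
  }
  tid <- mapply(truth_of, calls$x, calls$y)
  ok <- !is.na(tid)
  truth_class <- rendered$truth$class[match(tid[ok], rendered$truth$id)]
  matched <- data.frame(call_class = calls$class[ok],
                        truth_class = truth_class,
                        stringsAsFactors = FALSE)
  list(matched = matched,
       accuracy = if (nrow(matched) > 0)
         mean(matched$call_class == matched$truth_class) else NA_real_,
       n_unmatched = sum(!ok))
}

#' Render-and-call a small image cohort from case truth
#'
#' For each case and protein, renders `cores_per_case` synthetic cores whose
#' positive-epithelium fraction equals the case's latent positivity, calls
#' cells on each, and returns two cell-count tables: one aggregated from the
#' caller and one from the rendered per-nucleus truth.  Feeding both through
#' [score_cohort()] measures the end-to-end error the image pipeline adds to
#' the case-level minimum percent-positive score.
#'
#' @param truth rows of a [generate_cohort()] truth table (keep this small:
#'   each case renders `4 * cores_per_case` images).
#' @param cores_per_case cores rendered per case and protein.
#' @param n_epithelial epithelial nuclei per core.
#' @param diameter core diameter in pixels.
#' @param params caller parameters.
#' @param seed master seed.
#' @return list: `called_cells`, `truth_cells` (cell-count tables).
#' @export
simulate_image_cohort <- function(truth, cores_per_case = 1,
                                  n_epithelial = 260, diameter = 256,
                                  params = cell_caller_params(), seed = 5L) {
  called <- list(); exact <- list()
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    for (p in PROTEINS) {
      frac <- truth[[paste0("latent_", p)]][i]
      frac_s <- truth[[paste0("latent_str_", p)]][i]
      for (cc in seq_len(cores_per_case)) {
        k <- k + 1L
        spec <- simulate_core_spec(
          diameter = diameter, n_epithelial = n_epithelial,
          frac_pos_epithelial = frac,
          frac_pos_stromal = if (is.null(frac_s)) 0.85 else frac_s,
          seed = substream_seed(seed, k))
        rc <- render_core(spec)
        res <- call_cells(rc, params)
        core_id <- sprintf("%s_img%d", truth$case_id[i], cc)
        called[[length(called) + 1]] <-
          counts_to_row(res, truth$case_id[i], core_id, "TC", p)
        exact[[length(exact) + 1]] <-
          counts_to_row(rc, truth$case_id[i], core_id, "TC", p)
      }
    }
  }
  list(called_cells = do.call(rbind, called),
       truth_cells = do.call(rbind, exact))
}

#' Write a rendered core to PNG files
#'
#' @param rendered a `rendered_core`.
#' @param path output path for the RGB image (PNG); the label mask is
#'   written alongside as `<path>_mask.png` (16-bit).
#' @return `path`, invisibly.
#' @export
write_rendered_core <- function(rendered, path) {
  img <- EBImage::Image(rendered$rgb / 255, colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
  mask_path <- sub("\\.png$", "_mask.png", path)
  EBImage::writeImage(EBImage::Image(rendered$mask / 65535), mask_path,
                      type = "png", bits.per.sample = 16L)
  invisible(path)
}
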