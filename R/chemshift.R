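#' Chemical-shift perturbations for backbone amide probes
#'
#' Computes the weighted Euclidean CSP between two shift tables,
#' \eqn{\Delta\delta(HN) = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}},
#' per probe shared by both tables.
#'
#' @param reference,perturbed Tibbles with columns `residue`, `atom`,
#'   `nucleus` (`"1H"`/`"15N"` for amides, `"1H"`/`"13C"` for methyls) and
#'   `shift_ppm`.
#' @return A tibble with `residue`, `atom`, `delta_H`, `delta_X`, `csp`
#'   (all ppm). Probes present in only one table are recorded in
#'   `attr(, "unmatched")`.
#' @export
#' @examples
#' ref <- tibble::tibble(residue = 1, atom = "N-H",
#'                       nucleus = c("1H", "15N"), shift_ppm = c(8.0, 120))
#' per <- dplyr::mutate(ref, shift_ppm = shift_ppm + c(0.1, 0))
#' compute_csp_amide(ref, per)$csp  # 0.1
compute_csp_amide <- function(reference, perturbed) {
  .compute_csp(reference, perturbed, x_nucleus = "15N", x_divisor = 5)
}

#' Chemical-shift perturbations for methyl probes
#'
#' As [compute_csp_amide()] but with the carbon difference scaled by 4:
#' \eqn{\Delta\delta(HC) = \sqrt{\Delta\delta_H^2 + (\Delta\delta_C/4)^2}}.
#'
#' @inheritParams compute_csp_amide
#' @return See [compute_csp_amide()].
#' @export
compute_csp_methyl <- function(reference, perturbed) {
  .compute_csp(reference, perturbed, x_nucleus = "13C", x_divisor = 4)
}

.compute_csp <- function(reference, perturbed, x_nucleus, x_divisor) {
  wide <- function(tb) {
    tb |>
      filter(.data$nucleus %in% c("1H", x_nucleus)) |>
      tidyr::pivot_wider(id_cols = c("residue", "atom"),
                         names_from = "nucleus", values_from = "shift_ppm")
  }
  a <- wide(reference); b <- wide(perturbed)
  joined <- inner_join(a, b, by = c("residue", "atom"), suffix = c("_ref", "_per"))
  hr <- paste0("1H_ref"); hp <- paste0("1H_per")
  xr <- paste0(x_nucleus, "_ref"); xp <- paste0(x_nucleus, "_per")
  for (nm in c(hr, hp, xr, xp)) if (!nm %in% names(joined)) joined[[nm]] <- NA_real_
  joined <- filter(joined, !is.na(.data[[hr]]), !is.na(.data[[hp]]),
                   !is.na(.data[[xr]]), !is.na(.data[[xp]]))
  if (nrow(joined) == 0) {
    abort("Empty overlap: the two shift tables share no probe with both nuclei")
  }
  out <- joined |>
    mutate(
      delta_H = .data[[hp]] - .data[[hr]],
      delta_X = .data[[xp]] - .data[[xr]],
      csp = sqrt(.data$delta_H^2 + (.data$delta_X / x_divisor)^2)
    ) |>
    select("residue", "atom", "delta_H", "delta_X", "csp") |>
    arrange(.data$residue)
  key <- function(tb) paste(tb$residue, tb$atom)
  unmatched <- union(setdiff(key(a), key(b)), setdiff(key(b), key(a)))
  structure(out, unmatched = unmatched)
}

#' Flag significant chemical-shift perturbations
#'
#' Marks CSPs larger than the mean plus `k` standard deviations of the CSP
#' distribution. In `corrected_to_zero` mode the mean and SD are recomputed
#' iteratively over the not-yet-flagged records until the flagged set is
#' stable, so a few large perturbations do not inflate their own threshold.
#'
#' @param csps Tibble from [compute_csp_amide()]/[compute_csp_methyl()].
#' @param threshold_mode `"1SD"` or `"2SD"` (k = 1 or 2).
#' @param corrected_to_zero Use the iteratively trimmed statistic (default
#'   `FALSE`: a single pass over all records).
#' @return `csps` with added `significant` (`"none"` or the threshold mode)
#'   and attribute `threshold` (the final cutoff in ppm).
#' @export
flag_significant <- function(csps, threshold_mode = c("1SD", "2SD"),
                             corrected_to_zero = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  if (nrow(csps) < 3) abort("Need at least 3 CSP records to estimate a threshold")
  k <- if (threshold_mode == "1SD") 1 else 2
  x <- csps$csp
  if (sd(x) == 0) {
    warn("All CSPs identical: SD = 0, nothing flagged")
    return(structure(mutate(csps, significant = "none"), threshold = NA_real_))
  }
  flagged <- rep(FALSE, length(x))
  for (pass in seq_len(20)) {
    keep <- if (corrected_to_zero) !flagged else rep(TRUE, length(x))
    thr <- mean(x[keep]) + k * sd(x[keep])
    new_flagged <- x > thr
    if (identical(new_flagged, flagged) || !corrected_to_zero) {
      flagged <- new_flagged
      break
    }
    flagged <- new_flagged
  }
  structure(
    mutate(csps, significant = ifelse(flagged, threshold_mode, "none")),
    threshold = thr
  )
}

#' Smoothed combined secondary chemical shifts
#'
#' Raw secondary shift per residue:
#' \eqn{(\delta_{C\alpha} - \delta_{C\alpha,rc}) - (\delta_{C\beta} - \delta_{C\beta,rc})},
#' smoothed along the sequence with 1-2-1 weights over residues
#' (i-1, i, i+1); missing neighbours are dropped and the weights renormalised.
#'
#' @param observed Tibble with `residue`, `nucleus` (`"CA"`/`"CB"`),
#'   `shift_ppm`.
#' @param random_coil Same layout: random-coil reference shifts (an input
#'   table, e.g. from a published random-coil predictor).
#' @return Tibble with `residue`, `raw`, `smoothed` (ppm). Residues missing
#'   both nuclei are excluded with a warning.
#' @export
secondary_shifts <- function(observed, random_coil) {
  wide <- function(tb) tidyr::pivot_wider(tb, id_cols = "residue",
                                          names_from = "nucleus",
                                          values_from = "shift_ppm")
  obs <- wide(observed); rc <- wide(random_coil)
  j <- inner_join(obs, rc, by = "residue", suffix = c("_obs", "_rc"))
  for (nm in c("CA_obs", "CB_obs", "CA_rc", "CB_rc")) {
    if (!nm %in% names(j)) j[[nm]] <- NA_real_
  }
  dropped <- j$residue[is.na(j$CA_obs) & is.na(j$CB_obs)]
  if (length(dropped)) {
    warn(paste0("Residue(s) missing both CA and CB excluded: ",
                paste(dropped, collapse = ", ")))
  }
  # Glycine and incomplete residues: use whichever component is present
  j <- j |>
    mutate(
      d_ca = .data$CA_obs - .data$CA_rc,
      d_cb = .data$CB_obs - .data$CB_rc,
      raw = dplyr::coalesce(.data$d_ca, 0) - dplyr::coalesce(.data$d_cb, 0)
    ) |>
    filter(!(is.na(.data$d_ca) & is.na(.data$d_cb))) |>
    arrange(.data$residue)
  raw_at <- setNames(j$raw, j$residue)
  sm <- vapply(j$residue, function(r) {
    w <- c(1, 2, 1); v <- raw_at[as.character(c(r - 1, r, r + 1))]
    ok <- !is.na(v)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  tibble(residue = j$residue, raw = j$raw, smoothed = sm)
}

# Linear 13C shift calibrations for the trans-rotamer population.
.rotamer_cal <- list(
  "Ile-d1" = c(intercept = 9.3, slope = 5.5),
  "Met-e"  = c(intercept = 15.9, slope = 3.6)
)

#' Methyl rotamer populations from 13C chemical shifts
#'
#' The trans-rotamer population of the Ile chi2 or Met chi3 angle is obtained
#' from the linear calibration of the methyl 13C shift:
#' Met-epsilon \eqn{\delta_{obs} = 15.9 + 3.6\,p_{trans}}; Ile-delta1
#' \eqn{\delta_{obs} = 9.3 + 5.5\,p_{trans}}. Populations are clamped to
#' \[0, 1\] (with a warning) when the shift falls outside the calibration
#' range. Classes: `trans` for p_trans in \[0.75, 1\], `gauche_minus` for
#' \[0, 0.25\], otherwise `mixed`.
#'
#' @param shifts Tibble with `residue`, `atom` (`"Ile-d1"` or `"Met-e"`) and
#'   `shift_ppm` (the methyl 13C shift).
#' @return Tibble with added `p_trans` and `rotamer_class`.
#' @export
#' @examples
#' rotamer_population(tibble::tibble(residue = 1, atom = "Ile-d1",
#'                                   shift_ppm = 14.8))
rotamer_population <- function(shifts) {
  bad <- setdiff(unique(shifts$atom), names(.rotamer_cal))
  if (length(bad)) {
    abort(paste0("Rotamer calibration only defined for Ile-d1 and Met-e; got: ",
                 paste(bad, collapse = ", ")))
  }
  cal <- bind_rows(lapply(.rotamer_cal, \(v) tibble(intercept = v[1], slope = v[2])),
                   .id = "atom")
  out <- shifts |>
    left_join(cal, by = "atom") |>
    mutate(p_raw = (.data$shift_ppm - .data$intercept) / .data$slope,
           p_trans = pmin(1, pmax(0, .data$p_raw)))
  n_clamped <- sum(out$p_raw < 0 | out$p_raw > 1)
  if (n_clamped > 0) {
    warn(paste0(n_clamped, " probe(s) outside the calibration range; ",
                "p_trans clamped to [0, 1]"))
  }
  out |>
    mutate(rotamer_class = dplyr::case_when(
      .data$p_trans >= 0.75 ~ "trans",
      .data$p_trans <= 0.25 ~ "gauche_minus",
      TRUE ~ "mixed"
    )) |>
    select(-"intercept", -"slope", -"p_raw")
}

#' Change in rotamer populations between two states
#'
#' @param holo,apo Tibbles from [rotamer_population()].
#' @return Tibble with `residue`, `atom`, `p_trans_holo`, `p_trans_apo`,
#'   `delta_p_trans` (holo - apo) and `direction` (`toward_trans`,
#'   `toward_gauche_minus` or `unchanged`). Probes present in only one state
#'   are listed in `attr(, "unmatched")`.
#' @export
rotamer_delta <- function(holo, apo) {
  j <- inner_join(
    select(holo, "residue", "atom", p_trans_holo = "p_trans"),
    select(apo, "residue", "atom", p_trans_apo = "p_trans"),
    by = c("residue", "atom")
  )
  if (nrow(j) == 0) abort("Empty overlap: no shared probes between states")
  out <- j |>
    mutate(delta_p_trans = .data$p_trans_holo - .data$p_trans_apo,
           direction = dplyr::case_when(
             .data$delta_p_trans > 0 ~ "toward_trans",
             .data$delta_p_trans < 0 ~ "toward_gauche_minus",
             TRUE ~ "unchanged"
           ))
  key <- function(tb) paste(tb$residue, tb$atom)
  structure(out, unmatched = union(setdiff(key(holo), key(j)),
                                   setdiff(key(apo), key(j))))
}

.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' Build a methyl NOE contact network from a cross-peak list
#'
#' Symmetrises probe pairs into an undirected simple graph; reciprocal peaks
#' collapse onto one edge with their count and mean intensity. Self-pairs are
#' dropped with a warning.
#'
#' @param crosspeaks Tibble with columns `probe_a`, `probe_b` (probe labels,
#'   e.g. `"I373-d1"`) and optionally `intensity`.
#' @return Tibble of edges: `probe_a`, `probe_b` (sorted within the pair),
#'   `n_peaks`, `mean_intensity`.
#' @export
build_noe_network <- function(crosspeaks) {
  if (nrow(crosspeaks) == 0) {
    return(tibble(probe_a = character(0), probe_b = character(0),
                  n_peaks = integer(0), mean_intensity = numeric(0)))
  }
  if (!"intensity" %in% names(crosspeaks)) crosspeaks$intensity <- NA_real_
  selfp <- crosspeaks$probe_a == crosspeaks$probe_b
  if (any(selfp)) {
    warn(paste0(sum(selfp), " self-pair row(s) dropped"))
    crosspeaks <- crosspeaks[!selfp, , drop = FALSE]
  }
  crosspeaks |>
    mutate(a = pmin(.data$probe_a, .data$probe_b),
           b = pmax(.data$probe_a, .data$probe_b)) |>
    summarise(n_peaks = dplyr::n(),
              mean_intensity = mean(.data$intensity),
              .by = c("a", "b")) |>
    rename(probe_a = "a", probe_b = "b") |>
    arrange(.data$probe_a, .data$probe_b)
}

#' Difference between two NOE networks
#'
#' Edge-identity set algebra between two networks (intensities are ignored
#' unless `min_intensity` is given, in which case weaker edges are removed
#' from both networks first).
#'
#' @param a,b Edge tibbles from [build_noe_network()] (e.g. apo and holo).
#' @param min_intensity Optional intensity floor applied to both networks.
#' @return List of edge tibbles: `gained` (in `b` only), `lost` (in `a`
#'   only), `retained` (in both).
#' @export
diff_noe_networks <- function(a, b, min_intensity = NULL) {
  if (!is.null(min_intensity)) {
    a <- filter(a, .data$mean_intensity >= min_intensity)
    b <- filter(b, .data$mean_intensity >= min_intensity)
  }
  ka <- .edge_key(a$probe_a, a$probe_b)
  kb <- .edge_key(b$probe_a, b$probe_b)
  list(
    gained = b[!kb %in% ka, , drop = FALSE],
    lost = a[!ka %in% kb, , drop = FALSE],
    retained = a[ka %in% kb, , drop = FALSE]
  )
}
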