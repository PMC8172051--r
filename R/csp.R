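#' Weighted chemical shift perturbation
#'
#' Combined backbone-amide CSP from the proton and nitrogen shift
#' changes:
#'
#'   Delta-delta = sqrt( (Dh^2 + (Dn/5)^2) / 2 )
#'
#' The nitrogen scaling factor 5 and the 1/2 normalization define the
#' statistic and are not configurable. Signs do not matter (squaring).
#'
#' @param d_h change in amide 1H shift (ppm)
#' @param d_n change in amide 15N shift (ppm)
#' @return non-negative CSP (ppm), vectorized
#' @export
csp <- function(d_h, d_n) sqrt((d_h^2 + (d_n / 5)^2) / 2)

#' Construct a per-residue amide shift table
#'
#' One record per residue: amide proton and nitrogen shift (ppm).
#' Residues lacking an amide proton (prolines; the chain-initial residue
#' if `flag_first`) are flagged by setting their shifts to NA.
#'
#' @param resid residue indices
#' @param resname residue names (3-letter)
#' @param h,n amide 1H / 15N shifts (ppm)
#' @param state "apo" or "bound"
#' @param replicate replicate id
#' @param flag_first flag the first residue as amide-less (default FALSE)
#' @return data.frame of class `shift_table`
#' @export
shift_table <- function(resid, resname, h, n, state = c("apo", "bound"),
                        replicate = 1L, flag_first = FALSE) {
  state <- match.arg(state)
  stopifnot(length(resid) == length(resname), length(h) == length(resid),
            length(n) == length(resid))
  if (anyDuplicated(resid)) stop("shift_table: one record per residue required")
  amideless <- toupper(resname) == "PRO"
  if (flag_first) amideless[which.min(resid)] <- TRUE
  h[amideless] <- NA_real_
  n[amideless] <- NA_real_
  if (any(!is.finite(h[!amideless])) || any(!is.finite(n[!amideless])))
    stop("shift_table: shifts must be finite")
  out <- data.frame(resid = as.integer(resid), resname = resname,
                    h = h, n = n, state = state,
                    replicate = as.integer(replicate),
                    amideless = amideless, stringsAsFactors = FALSE)
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Read a per-residue shift table from CSV/TSV
#'
#' Accepts SHIFTX2-style long format (columns NUM, RES, ATOMNAME, SHIFT;
#' rows H and N are used) or a simplified wide table with columns
#' `resid`, `resname`, `h`, `n`.
#'
#' @param path file path
#' @param state,replicate recorded on the table
#' @export
read_shift_table <- function(path, state = c("apo", "bound"), replicate = 1L) {
  state <- match.arg(state)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- toupper(names(df))
  if (all(c("NUM", "RES", "ATOMNAME", "SHIFT") %in% nm)) {
    names(df) <- nm
    hh <- df[df$ATOMNAME == "H", ]
    nn <- df[df$ATOMNAME == "N", ]
    resid <- sort(unique(df$NUM))
    res <- df$RES[match(resid, df$NUM)]
    shift_table(resid, res,
                h = hh$SHIFT[match(resid, hh$NUM)],
                n = nn$SHIFT[match(resid, nn$NUM)],
                state = state, replicate = replicate)
  } else if (all(c("RESID", "RESNAME", "H", "N") %in% nm)) {
    names(df) <- nm
    shift_table(df$RESID, df$RESNAME, df$H, df$N, state = state,
                replicate = replicate)
  } else stop("unrecognized shift-table columns in ", path)
}

mean_shifts <- function(tables) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  resid <- sort(unique(df$resid))
  data.frame(resid = resid,
             resname = df$resname[match(resid, df$resid)],
             h = vapply(resid, function(r) mean(df$h[df$resid == r]), 1),
             n = vapply(resid, function(r) mean(df$n[df$resid == r]), 1),
             stringsAsFactors = FALSE)
}

#' Per-residue CSP profile from apo/bound replicate shift tables
#'
#' Shifts are averaged over replicates within each state first, then
#' differenced (bound - apo) and combined with the weighted-CSP formula.
#' Residues flagged amide-less in either state get a missing CSP (never
#' zero). When apo and bound replicate counts match, a per-replicate CSP
#' standard deviation is reported (replicates paired in order).
#'
#' @param apo,bound a `shift_table` or list of replicate `shift_table`s
#' @return data.frame of class `csp_table` with `resid`, `resname`,
#'   `d_h`, `d_n`, `csp`, `csp_sd`, `n_apo`, `n_bound`
#' @export
csp_profile <- function(apo, bound) {
  if (inherits(apo, "shift_table")) apo <- list(apo)
  if (inherits(bound, "shift_table")) bound <- list(bound)
  stopifnot(length(apo) >= 1, length(bound) >= 1)
  ma <- mean_shifts(apo)
  mb <- mean_shifts(bound)
  only_a <- setdiff(ma$resid, mb$resid)
  only_b <- setdiff(mb$resid, ma$resid)
  if (length(only_a) + length(only_b) > 0)
    stop("residues present in one state only: ",
         paste(c(only_a, only_b), collapse = ", "))
  d_h <- mb$h - ma$h
  d_n <- mb$n - ma$n
  val <- csp(d_h, d_n)
  csp_sd <- rep(NA_real_, nrow(ma))
  if (length(apo) == length(bound) && length(apo) > 1) {
    per <- vapply(seq_along(apo), function(r) {
      a <- as.data.frame(apo[[r]]); b <- as.data.frame(bound[[r]])
      i <- match(ma$resid, a$resid); j <- match(ma$resid, b$resid)
      csp(b$h[j] - a$h[i], b$n[j] - a$n[i])
    }, numeric(nrow(ma)))
    csp_sd <- apply(per, 1, stats::sd)
  }
  out <- data.frame(resid = ma$resid, resname = ma$resname,
                    d_h = d_h, d_n = d_n, csp = val, csp_sd = csp_sd,
                    n_apo = length(apo), n_bound = length(bound),
                    stringsAsFactors = FALSE)
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Threshold CSP hotspots
#'
#' Residues with CSP strictly above a cutoff. Rules: `"absolute"` (a ppm
#' value) or `"mean_sd"` (mean + k*sd over non-missing residues,
#' default k = 1). The numeric cutoff actually applied is attached as an
#' attribute and echoed by printing.
#'
#' @param csptab a `csp_table`
#' @param rule "mean_sd" or "absolute"
#' @param k multiplier for the sd rule
#' @param value ppm cutoff for the absolute rule
#' @return integer vector of residue ids with attribute `cutoff`
#' @export
threshold_residues <- function(csptab, rule = c("mean_sd", "absolute"),
                               k = 1, value = NULL) {
  rule <- match.arg(rule)
  v <- csptab$csp
  if (all(is.na(v))) stop("all CSP values missing")
  cut <- if (rule == "absolute") {
    if (is.null(value)) stop("absolute rule needs `value`")
    value
  } else mean(v, na.rm = TRUE) + k * stats::sd(v, na.rm = TRUE)
  res <- csptab$resid[!is.na(v) & v > cut]
  structure(res, cutoff = cut, rule = rule)
}

#' Concordance of contacts and chemical shift perturbations
#'
#' Quantifies whether the CSP profile tracks the ligand-contact profile:
#' Spearman rank correlation over common residues, Jaccard overlap of the
#' top-k sets by each measure, and a per-residue discordance flag where
#' one measure is in its top quartile while the other sits in its bottom
#' half (either direction).
#'
#' @param contact_profile named numeric vector of per-residue contact
#'   probabilities (names = residue ids)
#' @param csptab a `csp_table`
#' @param k top-k set size for the overlap (default 10)
#' @return list with `rank_correlation`, `jaccard_top_k`, `n_common`,
#'   and `discordant` data.frame
#' @export
contact_csp_concordance <- function(contact_profile, csptab, k = 10) {
  resid <- intersect(as.integer(names(contact_profile)),
                     csptab$resid[!is.na(csptab$csp)])
  if (length(resid) < 3) stop("fewer than 3 common residues")
  x <- as.numeric(contact_profile[as.character(resid)])
  y <- csptab$csp[match(resid, csptab$resid)]
  rho <- stats::cor(x, y, method = "spearman")
  top <- function(v) resid[order(-v, resid)][seq_len(min(k, length(resid)))]
  tx <- top(x); ty <- top(y)
  jac <- length(intersect(tx, ty)) / length(union(tx, ty))
  q_hi_x <- x >= stats::quantile(x, 0.75)
  q_hi_y <- y >= stats::quantile(y, 0.75)
  lo_x <- x <= stats::median(x)
  lo_y <- y <= stats::median(y)
  disc <- (q_hi_x & lo_y) | (q_hi_y & lo_x)
  list(rank_correlation = rho, jaccard_top_k = jac, n_common = length(resid),
       discordant = data.frame(resid = resid, contact = x, csp = y,
                               discordant = disc))
}
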