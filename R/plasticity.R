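# Site-by-site comparison of pre- and post-induction maps.

#' Per-site Z-score difference of a pre/post map pair
#'
#' Both maps must come from the same grid and site set and should be
#' standardized against the same (pooled) noise model so the difference
#' reflects response change, not noise re-estimation.
#'
#' @param pre,post [ConnectivityMap-class] objects on identical geometry.
#' @return data.frame: \code{site}, \code{ml_um}, \code{depth_row},
#'   \code{z_pre}, \code{z_post}, \code{delta_z}.
#' @export
deltaMap <- function(pre, post) {
  stopifnot(is(pre, "ConnectivityMap"), is(post, "ConnectivityMap"))
  gEq <- isTRUE(all.equal(pre@geometry@halfExtent, post@geometry@halfExtent)) &&
    isTRUE(all.equal(pre@geometry@step, post@geometry@step)) &&
    pre@geometry@nDepthRows == post@geometry@nDepthRows &&
    isTRUE(all.equal(pre@geometry@midlineOffset, post@geometry@midlineOffset))
  if (!gEq || !identical(pre@sites$site, post@sites$site) ||
      !isTRUE(all.equal(pre@sites$ml_um, post@sites$ml_um)))
    stop("pre and post maps must share geometry and site set", call. = FALSE)
  data.frame(site = pre@sites$site, ml_um = pre@sites$ml_um,
             depth_row = pre@sites$depth_row,
             z_pre = pre@sites$z, z_post = post@sites$z,
             delta_z = post@sites$z - pre@sites$z)
}

#' Classify per-site plasticity changes
#'
#' A site is \code{potentiated} iff its delta-Z strictly exceeds the
#' threshold and \code{depressed} iff delta-Z < -threshold; a potentiated
#' site that was silent in the initial map is reported as \code{awakened}
#' (a refinement of potentiated: awakened sites count among the potentiated
#' ones). Everything else is \code{unchanged}.
#'
#' @param deltaZ numeric per-site delta-Z.
#' @param preLabels per-site factor/character from [classifySites()] on the
#'   initial map.
#' @param threshold significance threshold on |delta-Z| (default 3.09).
#' @return factor with levels potentiated, depressed, awakened, unchanged.
#' @export
classifyChanges <- function(deltaZ, preLabels,
                            threshold = significanceThreshold()) {
  stopifnot(threshold > 0, length(deltaZ) == length(preLabels))
  cls <- rep("unchanged", length(deltaZ))
  cls[deltaZ > threshold] <- "potentiated"
  cls[deltaZ < -threshold] <- "depressed"
  cls[cls == "potentiated" & preLabels == "silent"] <- "awakened"
  factor(cls, levels = c("potentiated", "depressed", "awakened", "unchanged"))
}

#' Regression of plasticity against initial connection strength
#'
#' Ordinary least-squares slope and Pearson r of delta-Z against the
#' initial Z, summarizing whether strong connections tend to depress while
#' weak ones potentiate (a negative relationship).
#'
#' @param deltaZ per-site delta-Z.
#' @param initialZ per-site initial Z.
#' @return list with \code{slope} and \code{r}.
#' @export
deltaVsInitial <- function(deltaZ, initialZ) {
  if (length(deltaZ) < 3L) stop("need >= 3 sites", call. = FALSE)
  if (stats::sd(initialZ) == 0)
    stop("zero variance in initial Z; regression undefined", call. = FALSE)
  fit <- stats::lm(deltaZ ~ initialZ)
  r <- if (stats::sd(deltaZ) == 0) 0
       else .pearson(deltaZ, initialZ)
  list(slope = unname(stats::coef(fit)[2]), r = r)
}

#' Full plasticity comparison of a map pair
#'
#' Convenience wrapper: computes the per-site delta-Z, classifies each site
#' (using the pre map's significance labels), and fits the
#' delta-Z-versus-initial-Z regression.
#'
#' @param pre,post [ConnectivityMap-class] objects on identical geometry
#'   sharing a noise model.
#' @param threshold |delta-Z| significance threshold.
#' @return a [PlasticityResult-class].
#' @export
comparePlasticity <- function(pre, post,
                              threshold = significanceThreshold()) {
  d <- deltaMap(pre, post)
  preLab <- classifySites(d$z_pre, threshold = threshold)
  d$class <- as.character(classifyChanges(d$delta_z, preLab,
                                          threshold = threshold))
  reg <- deltaVsInitial(d$delta_z, d$z_pre)
  new("PlasticityResult", sites = d, slope = reg$slope, r = reg$r,
      threshold = threshold)
}

#' @rdname siteTable
#' @export
setMethod("siteTable", "PlasticityResult", function(x) x@sites)

setMethod("show", "PlasticityResult", function(object) {
  tab <- table(factor(object@sites$class,
                      levels = c("potentiated", "depressed", "awakened",
                                 "unchanged")))
  changed <- sum(tab[c("potentiated", "depressed", "awakened")])
  cat(sprintf("PlasticityResult: %d sites, %d changed (|dZ| > %.2f)\n",
              nrow(object@sites), changed, object@threshold))
  cat(sprintf("  potentiated %d (of which awakened %d), depressed %d\n",
              tab[["potentiated"]] + tab[["awakened"]], tab[["awakened"]],
              tab[["depressed"]]))
  cat(sprintf("  dZ ~ initial Z: slope = %.3f, r = %.3f\n",
              object@slope, object@r))
})
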