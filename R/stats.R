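#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Rank-based one-way comparison of delta values (or any measurement) across
#' regions, with tie correction, followed by pairwise Dunn z tests adjusted
#' for multiplicity (Holm by default).
#'
#' @param groups named list of numeric vectors, >= 2 groups, each n >= 2.
#' @param pAdjust multiplicity adjustment method for the Dunn tests
#'   (see \code{\link[stats]{p.adjust}}).
#' @return list(H, df, p.value, posthoc) where posthoc is a data.frame with
#'   columns group1, group2, z, p, p.adj.
#' @export
kwAnova <- function(groups, pAdjust = "holm") {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group supplied")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- kruskal.test(x, g)
  # Dunn: difference of mean ranks over the pooled ranking, tie-corrected
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  combs <- utils::combn(names(groups), 2)
  z <- apply(combs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    as.numeric((mr[pr[1]] - mr[pr[2]]) / se)
  })
  p <- 2 * pnorm(-abs(z))
  posthoc <- data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
                        p = p, p.adj = p.adjust(p, pAdjust))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, posthoc = posthoc)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of numeric vectors, >= 2 groups, each n >= 2.
#' @return list(F, df, p.value, posthoc) where posthoc has columns group1,
#'   group2, diff, lwr, upr, p.adj.
#' @export
anovaTukey <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups)))
  fit <- aov(y ~ g, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  posthoc <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p.adj = tk[, "p adj"],
                        row.names = NULL)
  list(F = sm[["F value"]][1], df = sm[["Df"]],
       p.value = sm[["Pr(>F)"]][1], posthoc = posthoc)
}

# Compact letter display from a pairwise significance table: groups not
# significantly different share a letter (insert-absorb construction).
letterDisplay <- function(groupNames, pairTable, alpha = 0.05) {
  k <- length(groupNames)
  sig <- matrix(FALSE, k, k, dimnames = list(groupNames, groupNames))
  for (i in seq_len(nrow(pairTable))) {
    a <- pairTable$group1[i]; b <- pairTable$group2[i]
    s <- is.finite(pairTable$p.adj[i]) && pairTable$p.adj[i] < alpha
    sig[a, b] <- s; sig[b, a] <- s
  }
  sets <- list(groupNames)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (si in seq_along(sets)) {
      s <- sets[[si]]
      if (all(c(groupNames[i], groupNames[j]) %in% s)) {
        sets[[si]] <- setdiff(s, groupNames[j])
        sets[[length(sets) + 1L]] <- setdiff(s, groupNames[i])
      }
    }
    # absorb duplicated/contained sets
    keep <- rep(TRUE, length(sets))
    for (a2 in seq_along(sets)) for (b2 in seq_along(sets)) {
      if (a2 != b2 && keep[a2] && keep[b2] &&
          all(sets[[a2]] %in% sets[[b2]])) keep[a2] <- FALSE
    }
    sets <- sets[keep]
  }
  letters_ <- letters[seq_along(sets)]
  vapply(groupNames, function(gn)
    paste(letters_[vapply(sets, function(s) gn %in% s, logical(1))],
          collapse = ""), character(1))
}

#' Automatic intact-CatSper1 classification rule
#'
#' Operationalizes the manual intact/non-intact assignment: a cell is called
#' CatSper1-intact when its quadrilateral delta reaches the threshold AND its
#' 70 percent continuity drop is censored (signal continuous to the tail end).
#'
#' @param delta per-cell delta value.
#' @param continuityCensored logical, TRUE when no sustained 70\% drop occurred.
#' @param deltaThreshold minimum delta for an intact call.
#' @return logical vector.
#' @export
classifyIntact <- function(delta, continuityCensored, deltaThreshold = 0.1) {
  delta >= deltaThreshold & continuityCensored
}

#' Per-region intact counts, proportions and letter-coded comparisons
#'
#' Aggregates intact flags per region and replicate experiment, reports the
#' mean proportion with its SEM across replicates, and letter-codes pairwise
#' differences (one-way ANOVA + Tukey on per-replicate proportions; regions
#' sharing no letter differ at the given alpha).
#'
#' @param observations data.frame with columns region, replicate, and one or
#'   more logical flag columns (e.g. intact_catsper, intact_acrosome).
#' @param flagColumns names of the logical columns to summarize.
#' @param alpha significance level for the letter display.
#' @return named list (one element per flag column) of data.frames with
#'   columns region, n_cells, n_intact, proportion, sem, letters.
#' @export
classifyCounts <- function(observations,
                           flagColumns = intersect(
                             c("intact_catsper", "intact_acrosome"),
                             names(observations)),
                           alpha = 0.05) {
  stopifnot(all(c("region", "replicate") %in% names(observations)))
  if (length(flagColumns) == 0L) stop("no flag columns present")
  regions <- unique(as.character(observations$region))
  out <- list()
  for (fc in flagColumns) {
    perRep <- stats::aggregate(observations[[fc]],
      by = list(region = observations$region,
                replicate = observations$replicate),
      FUN = mean)
    tab <- do.call(rbind, lapply(regions, function(r) {
      sel <- observations$region == r
      props <- perRep$x[perRep$region == r]
      data.frame(region = r, n_cells = sum(sel),
                 n_intact = sum(observations[[fc]][sel]),
                 proportion = mean(observations[[fc]][sel]),
                 sem = if (length(props) > 1)
                         sd(props) / sqrt(length(props)) else 0)
    }))
    lt <- rep("a", length(regions))
    grp <- split(perRep$x, perRep$region)[regions]
    if (length(regions) >= 2 && all(vapply(grp, length, integer(1)) >= 2) &&
        sd(perRep$x) > 0) {
      at <- anovaTukey(grp)
      lt <- letterDisplay(regions, at$posthoc, alpha)
    }
    tab$letters <- lt
    out[[fc]] <- tab
  }
  out
}

mdTable <- function(df, digits = 4) {
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else v
  df[] <- lapply(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Assemble a markdown run report
#'
#' A self-contained, deterministic (timestamp-free) report of a pipeline run:
#' the run configuration hash, the per-region delta table with group tests,
#' the sensitivity-vs-noise table, and the intact-classification counts.
#' Missing sections are named explicitly; an empty run yields a "no cells"
#' notice.
#'
#' @param outputs list with any of: deltaTable (data.frame), kw (kwAnova
#'   output), sensitivityTable (data.frame), counts (classifyCounts output),
#'   configHash (character).
#' @param path file to write; the report text is also returned invisibly.
#' @return invisibly, the report text.
#' @export
buildReport <- function(outputs, path = NULL) {
  ln <- c("# CatSperQuant run report", "")
  if (!is.null(outputs$configHash))
    ln <- c(ln, paste("Run configuration hash:", outputs$configHash), "")
  hasCells <- !is.null(outputs$deltaTable) && nrow(outputs$deltaTable) > 0 &&
    any(outputs$deltaTable$n > 0)
  if (!hasCells) {
    ln <- c(ln, "**No cells were analyzed in this run.**", "")
  } else {
    ln <- c(ln, "## Quadrilateral delta by region", "",
            mdTable(outputs$deltaTable), "")
    if (!is.null(outputs$kw)) {
      ln <- c(ln, sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g",
                          outputs$kw$H, outputs$kw$df, outputs$kw$p.value), "",
              mdTable(outputs$kw$posthoc), "")
    }
  }
  if (!is.null(outputs$sensitivityTable)) {
    ln <- c(ln, "## Detector sensitivity vs noise", "",
            mdTable(outputs$sensitivityTable), "")
  } else ln <- c(ln, "_Sensitivity-vs-noise table not provided._", "")
  if (!is.null(outputs$counts)) {
    for (nm in names(outputs$counts))
      ln <- c(ln, paste0("## Intact counts: ", nm), "",
              mdTable(outputs$counts[[nm]]), "")
  }
  txt <- paste(ln, collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
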