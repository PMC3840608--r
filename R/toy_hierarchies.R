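#' Generate toy drug and diagnosis hierarchies
#'
#' Builds a small, fully consistent stand-in for the real coding systems: a
#' 5-level drug tree whose codes have the ATC shape (widths 1/3/4/5/7, so
#' prefix truncation walks up the tree) and a diagnosis tree of 3-digit stems
#' with 4th and 5th digits, cross-mapped to a 4-level multi-level grouping in
#' the same tabular layout the real-file reader consumes. A configurable
#' fraction of diagnosis codes lacks the deepest grouping levels, emulating
#' diagnosis codes with no mapping at levels 3/4.
#'
#' The returned object also fixes, deterministically, the code pools used by
#' the event generator: per-dimension "background" pools for noise events, one
#' proxy code per latent confounder (drawn from the far end of each tree so
#' proxies never collide with the noise pools), and a designated sibling family
#' for the sub-threshold split.
#'
#' @param config a [sim_config()].
#' @return A list of class \code{toy_hierarchies} with elements \code{atc}
#'   (data.frame \code{code,name}), \code{ccs} (data.frame \code{icd9_code,
#'   ccs_level1..4}), \code{atc_leaves}, \code{dx_leaves}, \code{pools} (named
#'   list of per-dimension code pools), \code{proxy} (data.frame
#'   \code{confounder, dimension, code}) and \code{split} (list with
#'   \code{parent}, \code{children}, \code{confounder}).
#' @export
generate_toy_hierarchies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  br <- config$hierarchy_branching

  atc <- build_atc_tree(br$atc)
  dxl <- build_dx_leaves(br$dx)
  ccs <- build_ccs_map(dxl, br$dx, config$ccs_missing_fraction,
                       child_seed(config$seed, 2L))

  leaves <- atc$leaves
  npool <- config$codes_per_dimension
  b5 <- br$atc[5]
  n_parents <- length(leaves) %/% b5

  # noise pools: leading stretch of each tree; proxies come from the tail
  if (npool > length(leaves) - 2L * b5)
    stop("codes_per_dimension too large for the drug tree; increase branching")
  if (npool > length(dxl) - br$dx[3] * 4L)
    stop("codes_per_dimension too large for the diagnosis tree; increase branching")
  pools <- list(
    pharmacy      = leaves[seq_len(npool)],
    dx_inpatient  = dxl[seq_len(npool)],
    dx_outpatient = dxl[seq_len(npool)],
    px_inpatient  = sprintf("%05d", 40000L + seq_len(npool)),
    px_outpatient = sprintf("%05d", 50000L + seq_len(npool))
  )

  # the split family: the last level-4 parent and its children
  split_children <- leaves[(n_parents - 1L) * b5 + seq_len(min(config$split_n_children, b5))]
  split_parent <- substr(split_children[1L], 1L, 5L)

  proxy <- assign_proxy_codes(config, leaves, dxl, pools, split_children)

  structure(list(atc = atc$table, ccs = ccs,
                 atc_leaves = leaves, dx_leaves = dxl,
                 pools = pools, proxy = proxy,
                 split = list(parent = split_parent, children = split_children,
                              confounder = config$n_confounders)),
            class = "toy_hierarchies")
}

# 5-level tree with ATC-shaped codes: letter, +2 digits, +letter, +letter, +2 digits
build_atc_tree <- function(branching) {
  b <- as.integer(branching)
  if (b[1] > 26L || b[3] > 26L || b[4] > 26L || b[2] > 99L || b[5] > 99L)
    stop("drug-tree branching exceeds the code alphabet")
  l1 <- LETTERS[seq_len(b[1])]
  l2 <- as.vector(outer(l1, sprintf("%02d", seq_len(b[2])), paste0))
  l3 <- as.vector(outer(sort(l2), LETTERS[seq_len(b[3])], paste0))
  l4 <- as.vector(outer(sort(l3), LETTERS[seq_len(b[4])], paste0))
  l5 <- as.vector(outer(sort(l4), sprintf("%02d", seq_len(b[5])), paste0))
  l5 <- sort(l5)
  all_codes <- c(l1, sort(l2), sort(l3), sort(l4), l5)
  list(table = data.frame(code = all_codes,
                          name = paste("drug group", all_codes),
                          stringsAsFactors = FALSE),
       leaves = l5)
}

# diagnosis leaves: 3-digit stems 400, 401, ... with a 4th and 5th digit
build_dx_leaves <- function(branching) {
  b <- as.integer(branching)
  stems <- sprintf("%03d", 399L + seq_len(b[1]))
  l4 <- as.vector(outer(stems, as.character(seq_len(b[2]) - 1L), paste0))
  sort(as.vector(outer(sort(l4), as.character(seq_len(b[3]) - 1L), paste0)))
}

# 4-level grouping over the diagnosis leaves; level1 pools ~4 stems, level2 is
# the stem, levels 3/4 follow the digits; a fraction of leaves loses its
# deepest level(s)
build_ccs_map <- function(dx_leaves, branching, missing_fraction, seed) {
  stem <- substr(dx_leaves, 1L, 3L)
  stem_idx <- as.integer(factor(stem, levels = unique(stem)))
  g1 <- ceiling(stem_idx / 4)
  lvl1 <- as.character(g1)
  lvl2 <- paste(g1, stem_idx, sep = ".")
  lvl3 <- paste(lvl2, as.integer(substr(dx_leaves, 4L, 4L)) + 1L, sep = ".")
  lvl4 <- paste(lvl3, as.integer(substr(dx_leaves, 5L, 5L)) + 1L, sep = ".")
  map <- data.frame(icd9_code = dx_leaves, ccs_level1 = lvl1, ccs_level2 = lvl2,
                    ccs_level3 = lvl3, ccs_level4 = lvl4,
                    stringsAsFactors = FALSE)
  if (missing_fraction > 0) {
    n_miss <- floor(missing_fraction * nrow(map))
    if (n_miss > 0) {
      drop4 <- with_local_seed(seed, sample.int(nrow(map), n_miss))
      map$ccs_level4[drop4] <- NA_character_
      drop3 <- drop4[seq_len(n_miss %/% 2L)]
      map$ccs_level3[drop3] <- NA_character_
    }
  }
  map
}

# deterministically place each latent confounder's proxy code; the designated
# split confounder is always a pharmacy code (the first split child)
assign_proxy_codes <- function(config, atc_leaves, dx_leaves, pools, split_children) {
  k <- config$n_confounders
  if (k == 0L)
    return(data.frame(confounder = integer(), dimension = character(),
                      code = character(), stringsAsFactors = FALSE))
  b5 <- config$hierarchy_branching$atc[5]
  n_parents <- length(atc_leaves) %/% b5
  # pharmacy proxies: first leaf of each parent, from the tail, skipping the
  # split parent (the last one)
  rx_candidates <- setdiff(atc_leaves[((n_parents - 1L):1L - 1L) * b5 + 1L],
                           pools$pharmacy)
  dx_candidates <- setdiff(rev(dx_leaves), pools$dx_inpatient)
  dims <- rep(c("pharmacy", "dx_outpatient", "dx_inpatient"), length.out = k)
  dims[k] <- "pharmacy"
  code <- character(k)
  i_rx <- 0L; i_dx <- 0L
  for (j in seq_len(k)) {
    if (j == k) {                       # designated split confounder
      code[j] <- split_children[1L]
    } else if (dims[j] == "pharmacy") {
      i_rx <- i_rx + 1L
      if (i_rx > length(rx_candidates)) stop("drug tree too small for proxies")
      code[j] <- rx_candidates[i_rx]
    } else {
      i_dx <- i_dx + 1L
      if (i_dx > length(dx_candidates))
        stop("diagnosis tree too small for proxies")
      code[j] <- dx_candidates[i_dx]
    }
  }
  if (anyDuplicated(code[dims == "pharmacy"]))
    stop("drug tree too small: proxy codes collide")
  data.frame(confounder = seq_len(k), dimension = dims, code = code,
             stringsAsFactors = FALSE)
}
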