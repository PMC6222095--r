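#' Chain topology for a multidomain protein
#'
#' Describes how a chain of short consensus/complement-repeat-like domains
#' is laid out along the sequence: the residue range of each domain, the 19
#' inter-domain linkers split into movable and fixed sets, the residues
#' carrying N-glycans, and the central residue range used as the reference
#' frame for superposition.
#'
#' @param domain_ranges integer matrix (n_domains x 2) of first/last residue
#'   per domain, ordered and non-overlapping.
#' @param movable_linkers list of `c(first, last)` residue ranges whose
#'   backbone torsions are sampled.
#' @param fixed_linkers list of residue ranges held rigid.
#' @param glycan_sites integer vector of residues carrying glycans; each
#'   must fall inside a domain range.
#' @param reference_domains `c(first, last)` residue range used for
#'   superposition (the structurally central domains).
#' @return object of class `chain_topology`.
#' @export
chain_topology <- function(domain_ranges, movable_linkers, fixed_linkers,
                           glycan_sites, reference_domains) {
  dr <- as.matrix(domain_ranges)
  if (ncol(dr) != 2) stop("domain_ranges must have two columns")
  if (any(dr[, 1] > dr[, 2])) stop("domain ranges must have first <= last")
  if (nrow(dr) > 1 && any(dr[-1, 1] <= dr[-nrow(dr), 2]))
    stop("domain ranges must be ordered and non-overlapping")
  n_link <- nrow(dr) - 1
  if (length(movable_linkers) + length(fixed_linkers) != n_link)
    stop(sprintf("movable + fixed linkers must cover all %d inter-domain linkers",
                 n_link))
  in_domain <- function(r) any(r >= dr[, 1] & r <= dr[, 2])
  if (!all(vapply(glycan_sites, in_domain, logical(1))))
    stop("every glycan site must fall inside a domain range")
  structure(
    list(domain_ranges = unname(dr),
         movable_linkers = lapply(movable_linkers, as.integer),
         fixed_linkers = lapply(fixed_linkers, as.integer),
         glycan_sites = as.integer(glycan_sites),
         reference_domains = as.integer(reference_domains)),
    class = "chain_topology"
  )
}

#' Default 20-domain chain topology
#'
#' A factor H-like layout: 20 domains of ~61 residues joined by 19 linkers
#' of 3-8 residues, of which the 8 linkers after domains 4, 5, 8, 9, 13, 14,
#' 16 and 17 are movable (the conserved half-cystine positions at the ends
#' of each linker are never rotated). Eight glycan attachment sites sit on
#' domains 9, 12, 13, 14, 15 (twice), 17 and 19. Domains 10-13 are the
#' superposition reference.
#'
#' @param n_domains number of domains.
#' @param domain_len residues per domain.
#' @param movable_after domain indices whose following linker is movable.
#' @param movable_len,fixed_len linker lengths in residues.
#' @return a `chain_topology`.
#' @export
fh_topology <- function(n_domains = 20, domain_len = 61,
                        movable_after = c(4, 5, 8, 9, 13, 14, 16, 17),
                        movable_len = 6, fixed_len = 4) {
  linker_len <- ifelse(seq_len(n_domains - 1) %in% movable_after,
                       movable_len, fixed_len)
  dr <- matrix(0L, n_domains, 2)
  pos <- 1L
  movable <- list(); fixed <- list()
  for (i in seq_len(n_domains)) {
    dr[i, ] <- c(pos, pos + domain_len - 1L)
    pos <- pos + domain_len
    if (i < n_domains) {
      rng <- c(pos, pos + linker_len[i] - 1L)
      if (i %in% movable_after) movable <- c(movable, list(rng))
      else fixed <- c(fixed, list(rng))
      pos <- pos + linker_len[i]
    }
  }
  glycan_domains <- c(9, 12, 13, 14, 15, 15, 17, 19)
  sites <- integer(0)
  seen <- integer(0)
  for (d in glycan_domains) {
    k <- sum(seen == d)
    frac <- if (k == 0) 0.5 else 0.75
    sites <- c(sites, dr[d, 1] + as.integer(frac * (domain_len - 1)))
    seen <- c(seen, d)
  }
  ref <- c(dr[min(10, n_domains - 1), 1], dr[min(13, n_domains), 2])
  chain_topology(dr, movable, fixed, sites, ref)
}

#' Map residues to domains
#' @param topology a `chain_topology`.
#' @param resno integer residue numbers.
#' @return integer domain ids (NA for linker residues).
#' @export
domain_of_residue <- function(topology, resno) {
  dr <- topology$domain_ranges
  out <- rep(NA_integer_, length(resno))
  for (i in seq_len(nrow(dr)))
    out[resno >= dr[i, 1] & resno <= dr[i, 2]] <- i
  out
}

#' Residues whose torsions may be sampled
#'
#' Interior residues of the movable linkers: the first and last residue of
#' each linker flank the conserved cysteines and are excluded by default.
#'
#' @param topology a `chain_topology`.
#' @param exclude_cys_flanks drop the first/last residue of each linker.
#' @return integer vector of residue numbers.
#' @export
movable_residues <- function(topology, exclude_cys_flanks = TRUE) {
  unlist(lapply(topology$movable_linkers, function(r) {
    s <- seq.int(r[1], r[2])
    if (exclude_cys_flanks && length(s) > 2) s <- s[-c(1, length(s))]
    else if (exclude_cys_flanks) s <- integer(0)
    s
  }))
}

#' Read or write a chain topology as YAML
#'
#' @param path file path.
#' @return `read_topology` returns a `chain_topology`; `write_topology`
#'   returns the path invisibly.
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  chain_topology(
    do.call(rbind, lapply(y$domains, function(d) c(d$first, d$last))),
    lapply(Filter(function(l) isTRUE(l$movable), y$linkers),
           function(l) c(l$first, l$last)),
    lapply(Filter(function(l) !isTRUE(l$movable), y$linkers),
           function(l) c(l$first, l$last)),
    unlist(y$glycan_sites),
    c(y$reference_domains$first, y$reference_domains$last)
  )
}

#' @rdname read_topology
#' @param topology a `chain_topology`.
#' @export
write_topology <- function(topology, path) {
  mk <- function(r, mov) list(first = r[1], last = r[2], movable = mov)
  links <- c(lapply(topology$movable_linkers, mk, mov = TRUE),
             lapply(topology$fixed_linkers, mk, mov = FALSE))
  links <- links[order(vapply(links, `[[`, 0, "first"))]
  y <- list(
    domains = apply(topology$domain_ranges, 1,
                    function(r) list(first = r[1], last = r[2]), simplify = FALSE),
    linkers = links,
    glycan_sites = as.list(topology$glycan_sites),
    reference_domains = list(first = topology$reference_domains[1],
                             last = topology$reference_domains[2])
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
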