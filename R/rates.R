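# Nei-Gojobori (1986) counting estimation of synonymous (dS) and
# nonsynonymous (dN) substitutions per site with Jukes-Cantor correction,
# and conversion to absolute rates per site per billion years by dividing
# by branch age.

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  bases <- c("A", "C", "G", "T")
  # per-codon synonymous site counts: at each position the synonymous
  # fraction among non-stop single-nucleotide changes
  syn_sites <- setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    sp <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      alt <- bases[bases != sp[p]]
      neigh <- vapply(alt, function(b) {
        x <- sp
        x[p] <- b
        paste(x, collapse = "")
      }, character(1))
      n_aa <- gc[neigh]
      nonstop <- n_aa != "*"
      if (any(nonstop)) {
        s <- s + sum(n_aa[nonstop] == gc[[cd]]) / sum(nonstop)
      }
    }
    syn_sites[cd] <- s
  }
  # pairwise synonymous/nonsynonymous difference counts with equal-weight
  # pathway averaging; pathways through stop codons are excluded (with a
  # fallback to all pathways, stop steps counted as nonsynonymous)
  path_count <- function(c1, c2) {
    s1 <- strsplit(c1, "")[[1]]
    s2 <- strsplit(c2, "")[[1]]
    dpos <- which(s1 != s2)
    nd <- length(dpos)
    if (nd == 0) return(c(0, 0))
    count_path <- function(order, allow_stop) {
      cur <- s1
      sd <- 0
      ndn <- 0
      for (p in order) {
        nxt <- cur
        nxt[p] <- s2[p]
        a1 <- gc[[paste(cur, collapse = "")]]
        a2 <- gc[[paste(nxt, collapse = "")]]
        if (a2 == "*" && !allow_stop) return(NULL)
        if (a1 == a2 && a2 != "*") sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      c(sd, ndn)
    }
    orders <- perms_of(dpos)
    res <- purrr::compact(lapply(orders, count_path, allow_stop = FALSE))
    if (!length(res)) {
      res <- lapply(orders, count_path, allow_stop = TRUE)
    }
    Reduce(`+`, res) / length(res)
  }
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- path_count(sense[i], sense[j])
      sd_mat[i, j] <- cnt[1]
      nd_mat[i, j] <- cnt[2]
    }
  }
  codon_env$tab <- list(gc = gc, sense = sense, syn_sites = syn_sites,
                        sd = sd_mat, nd = nd_mat)
  codon_env$tab
}

perms_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of codons
#'
#' For each codon position, the synonymous fraction among the non-stop
#' single-nucleotide neighbours; summed over the three positions this gives
#' the synonymous site count S, with N = 3 - S (stop neighbours are
#' excluded from the denominator, the classic counting convention).
#'
#' @param codons Character vector of sense codons.
#' @return Tibble: `codon`, `S`, `N`.
#' @export
ng86_site_counts <- function(codons) {
  tab <- codon_tables()
  codons <- toupper(codons)
  bad <- !(codons %in% tab$sense)
  if (any(bad)) {
    stop(sprintf("not a sense codon: %s",
                 paste(unique(codons[bad]), collapse = ", ")))
  }
  s <- unname(tab$syn_sites[codons])
  tibble(codon = codons, S = s, N = 3 - s)
}

split_codons <- function(x) {
  x <- toupper(x)
  if (nchar(x) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Pairwise dS/dN by Nei-Gojobori counting
#'
#' Codons containing gaps, ambiguity characters or stops in either sequence
#' are masked. Differences are counted with equal-weight averaging over all
#' mutational pathways of multi-hit codons (pathways through stop codons
#' excluded); proportions are corrected with the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4/3 p)`. Proportions at or above 3/4 are flagged
#' saturated and yield `NA` distances.
#'
#' @param a,b In-frame aligned coding sequences (equal length, divisible
#'   by 3), or character vectors of codons.
#' @return One-row `mm_ng86` tibble: `n_codons`, `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `saturated_S`,
#'   `saturated_N`.
#' @export
ng86_pairwise <- function(a, b) {
  tab <- codon_tables()
  ca <- if (length(a) > 1) toupper(a) else split_codons(a)
  cb <- if (length(b) > 1) toupper(b) else split_codons(b)
  if (length(ca) != length(cb)) stop("sequences differ in codon count")
  ok <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[ok]
  cb <- cb[ok]
  n <- length(ca)
  if (n == 0) stop("no unmasked codons")
  if (n < 30) warning("fewer than 30 unmasked codons; estimates unstable")
  s_a <- sum(tab$syn_sites[ca])
  s_b <- sum(tab$syn_sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * n - S
  idx <- cbind(match(ca, tab$sense), match(cb, tab$sense))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  out <- tibble(n_codons = n, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                pS = pS, pN = pN, dS = dS, dN = dN,
                omega = ifelse(!is.na(dS) && dS > 0, dN / dS, NA_real_),
                saturated_S = pS >= 3 / 4, saturated_N = pN >= 3 / 4)
  structure(out, class = c("mm_ng86", class(tibble())))
}

#' All pairwise dS/dN over a codon alignment
#'
#' @param aln Named character vector of in-frame aligned coding sequences.
#' @return `mm_ng86` tibble with one row per unordered taxon pair, plus
#'   `taxon_a`, `taxon_b` columns.
#' @export
ng86_pairwise_all <- function(aln) {
  stopifnot(length(aln) >= 2, !is.null(names(aln)))
  taxa <- names(aln)
  out <- list()
  for (i in seq_len(length(aln) - 1)) {
    for (j in seq(i + 1, length(aln))) {
      r <- ng86_pairwise(aln[[i]], aln[[j]])
      out[[length(out) + 1]] <- mutate(as_tibble(r),
        taxon_a = taxa[i], taxon_b = taxa[j], .before = 1)
    }
  }
  structure(bind_rows(out), class = c("mm_ng86", class(tibble())))
}

#' Absolute substitution rate per site per billion years
#'
#' Divides a substitution estimate (substitutions per site) by the branch
#' age expressed in billions of years.
#'
#' @param d Substitutions per site.
#' @param age_myr Branch age in millions of years (> 0).
#' @return Rate per site per billion years.
#' @export
absolute_rate <- function(d, age_myr) {
  if (any(age_myr <= 0)) stop("branch age must be positive")
  d / (age_myr / 1000)
}

#' Attach absolute rates to per-branch substitution estimates
#'
#' @param rates Tibble with columns `branch`, `dS`, `dN`.
#' @param ages Tibble with columns `branch`, `age_myr`.
#' @return `mm_rates` tibble with added `age_myr`, `R_S`, `R_N` (per site
#'   per billion years).
#' @export
rate_table <- function(rates, ages) {
  stopifnot(all(c("branch", "dS", "dN") %in% names(rates)),
            all(c("branch", "age_myr") %in% names(ages)))
  out <- left_join(rates, ages, by = "branch")
  if (any(is.na(out$age_myr))) {
    stop(sprintf("missing branch age for: %s",
                 paste(out$branch[is.na(out$age_myr)], collapse = ", ")))
  }
  out <- mutate(out, R_S = absolute_rate(.data$dS, .data$age_myr),
                R_N = absolute_rate(.data$dN, .data$age_myr))
  structure(out, class = c("mm_rates", class(tibble())))
}

#' Read a branch-age table
#'
#' @param path TSV with columns `branch`, `age_myr`.
#' @return Tibble.
#' @export
read_branch_ages <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}
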