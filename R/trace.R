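# Identity-by-descent haplotype tracking: each seedling haplotype is given
# a parental origin outcome and walked up the pedigree until a terminal
# ancestor (unknown parents, no genotype data, or no carrying parent).

#' Assign the parental origin of a haplotype
#'
#' Compares a haplotype string with one parent's two haplotypes. An exact
#' match is `identical`; a unique match after filling at most `max_impute`
#' missing alleles is `imputed`; no compatible string but a unique
#' primary-SNP allele match is `recombinant`; anything else (zero or
#' several candidates, too many missing alleles) is `unassignable`. An
#' unknown parent (`NULL`/`NA` pair) yields `terminal-unknown`.
#'
#' @param hap Haplotype string (`A`, `B`, `-`).
#' @param parent_pair Character vector of the parent's two haplotype
#'   strings (may contain `-`), or `NULL`/`NA` when the parent is unknown.
#' @param ps_index 1-based primary-SNP position within the block.
#' @param max_impute Maximum missing alleles counted as "easily imputed"
#'   (default 2).
#' @return List `outcome` (one of `identical, imputed, recombinant,
#'   unassignable, terminal-unknown`) and `matched` (the matched parental
#'   string, or `NA`).
#' @export
assign_origin <- function(hap, parent_pair, ps_index, max_impute = 2) {
  parent_pair <- parent_pair[!is.na(parent_pair)]
  if (length(parent_pair) == 0) {
    return(list(outcome = "terminal-unknown", matched = NA_character_))
  }
  hs <- strsplit(hap, "", fixed = TRUE)[[1]]
  cand <- map(unique(parent_pair), function(p) {
    ps <- strsplit(p, "", fixed = TRUE)[[1]]
    if (length(ps) != length(hs)) {
      stop_bad_input("haplotype strings must share the block length")
    }
    known <- hs != "-" & ps != "-"
    list(string = p,
         mismatches = sum(hs[known] != ps[known]),
         n_missing = sum(hs == "-" | ps == "-"))
  })
  compat <- Filter(function(r) r$mismatches == 0, cand)
  if (length(compat) == 1) {
    r <- compat[[1]]
    if (r$n_missing == 0) {
      return(list(outcome = "identical", matched = r$string))
    }
    if (r$n_missing <= max_impute) {
      return(list(outcome = "imputed", matched = r$string))
    }
    return(list(outcome = "unassignable", matched = NA_character_))
  }
  if (length(compat) > 1) {
    return(list(outcome = "unassignable", matched = NA_character_))
  }
  # no compatible parental string: recombinant resolution by the PS allele
  ps_allele <- substr(hap, ps_index, ps_index)
  if (ps_allele %in% c("A", "B")) {
    hits <- Filter(function(r) substr(r$string, ps_index, ps_index) == ps_allele,
                   cand)
    if (length(hits) == 1) {
      return(list(outcome = "recombinant", matched = hits[[1]]$string))
    }
  }
  list(outcome = "unassignable", matched = NA_character_)
}

#' Trace a haplotype to its terminal ancestor(s)
#'
#' Walks up the pedigree from `id`, at each generation matching the current
#' haplotype string against each parent's diplotype with [assign_origin()].
#' An `identical`/`imputed` parent continues the walk (with the matched
#' parental string); when both parents carry it (inbreeding loops), both
#' branches are traced and all terminals reported. A `recombinant` or
#' `unassignable` outcome, unknown parents, or parents without phased data
#' terminate the branch. No individual is visited twice.
#'
#' @param id Individual whose haplotype is traced.
#' @param block_id Haploblock.
#' @param hap The haplotype string carried by `id` at the block.
#' @param pedigree Validated pedigree tibble.
#' @param phased Phased-haploblock tibble (`id, block_id, hap1, hap2`).
#' @param ps_index 1-based primary-SNP position within the block.
#' @param max_impute Passed to [assign_origin()].
#' @return An object of class `lineage_trace`: list with `id`, `block_id`,
#'   `hap`, `paths` (list of step tibbles `ancestor_id, outcome`),
#'   `terminals` (character vector of terminal ancestors) and `n_steps`
#'   (length of the longest path).
#' @export
trace_to_terminal <- function(id, block_id, hap, pedigree, phased,
                              ps_index = 1L, max_impute = 2) {
  pedigree <- validate_pedigree(pedigree)
  ph <- filter(phased, .data$block_id == !!block_id)
  pair_of <- function(ind) {
    r <- ph[ph$id == ind, ]
    if (nrow(r) == 0) return(NULL)
    c(r$hap1[1], r$hap2[1])
  }
  mothers <- setNames(pedigree$mother, pedigree$id)
  fathers <- setNames(pedigree$father, pedigree$id)
  walk <- function(ind, cur_hap, visited) {
    mo <- mothers[[ind]]; fa <- fathers[[ind]]
    if (is.na(mo) && is.na(fa)) {
      return(list(list(steps = tibble(ancestor_id = character(),
                                      outcome = character()),
                       terminal = ind)))
    }
    parents <- unique(stats::na.omit(c(mo, fa)))
    parents <- setdiff(parents, visited)
    if (length(parents) == 0) {
      return(list(list(steps = tibble(ancestor_id = character(),
                                      outcome = character()),
                       terminal = ind)))
    }
    origins <- map(parents, function(p) {
      pp <- pair_of(p)
      if (is.null(pp)) list(outcome = "no-data", matched = NA_character_)
      else assign_origin(cur_hap, pp, ps_index, max_impute)
    })
    names(origins) <- parents
    carrying <- parents[map_chr(origins, "outcome") %in% c("identical", "imputed")]
    if (length(carrying) == 0) {
      # record the blocking outcome (recombinant/unassignable) if any parent
      # had data, then terminate here
      informative <- Filter(function(o) o$outcome %in% c("recombinant", "unassignable"),
                            origins)
      if (length(informative)) {
        p1 <- names(informative)[1]
        return(list(list(
          steps = tibble(ancestor_id = p1,
                         outcome = informative[[p1]]$outcome),
          terminal = ind
        )))
      }
      return(list(list(steps = tibble(ancestor_id = character(),
                                      outcome = character()),
                       terminal = ind)))
    }
    out <- list()
    for (p in carrying) {
      sub <- walk(p, origins[[p]]$matched, c(visited, ind, carrying))
      for (s in sub) {
        out[[length(out) + 1L]] <- list(
          steps = bind_rows(tibble(ancestor_id = p,
                                   outcome = origins[[p]]$outcome),
                            s$steps),
          terminal = s$terminal
        )
      }
    }
    out
  }
  paths <- walk(id, hap, character(0))
  structure(
    list(id = id, block_id = block_id, hap = hap,
         paths = map(paths, "steps"),
         terminals = unique(map_chr(paths, "terminal")),
         n_steps = max(map_int(paths, function(p) nrow(p$steps)))),
    class = "lineage_trace"
  )
}

#' @export
print.lineage_trace <- function(x, ...) {
  cat("Haplotype trace:", x$id, "@", x$block_id, "(", x$hap, ")\n")
  for (p in x$paths) {
    if (nrow(p) == 0) {
      cat("  <founder: terminal is the individual itself>\n")
    } else {
      cat("  ", paste(sprintf("%s[%s]", p$ancestor_id, p$outcome),
                      collapse = " -> "), "\n")
    }
  }
  cat("terminal ancestor(s):", paste(x$terminals, collapse = ", "), "\n")
  invisible(x)
}

#' Trace every haplotype instance of a set of seedlings
#'
#' Convenience wrapper running [trace_to_terminal()] over both strands of
#' each seedling at one block.
#'
#' @inheritParams trace_to_terminal
#' @param ids Seedling ids to trace.
#' @return Tibble `id, strand, hap, terminals (list), n_steps`.
#' @export
trace_block <- function(ids, block_id, pedigree, phased, ps_index = 1L,
                        max_impute = 2) {
  ph <- filter(phased, .data$block_id == !!block_id, .data$id %in% ids)
  rows <- pmap(ph[c("id", "hap1", "hap2")], function(id, hap1, hap2) {
    map2(c("hap1", "hap2"), c(hap1, hap2), function(strand, h) {
      tr <- trace_to_terminal(id, block_id, h, pedigree, phased,
                              ps_index, max_impute)
      tibble(id = id, strand = strand, hap = h,
             terminals = list(tr$terminals), n_steps = tr$n_steps)
    }) |> list_rbind()
  })
  list_rbind(rows)
}
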