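---
title: "Prioritizing variants in a family quad: models, filters and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing variants in a family quad: models, filters and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A sporadic, severe Mendelian phenotype in a single affected individual —
here the motivating case is a myofibrillar myopathy — leaves too little
linkage information to map a locus, but exome sequencing of the nuclear
family turns the problem into one of *genotype-configuration filtering*:
among tens of thousands of coding variants, only a handful are compatible
with the observed affection pattern of a quad in which exactly one child is
affected and both parents and the other child are healthy. `quadprio`
implements that filtering cascade as a deterministic, fully traced pipeline,
together with a pedigree genotype simulator that makes every stage testable
without access to any real cohort.

## The cascade

Stages run in a fixed order; each record fails at most once, with a single
machine-readable reason, so stage counts always conserve the input
(`input = passes + per-reason failures`).

1. **Genotype quality.** Every member of the quad must have a fully called
   genotype with `GQ >= 50` and `DP >= 7` (boundaries inclusive: the rule
   discards calls strictly *below* the thresholds). The cut is applied
   per-sample over all four members, not proband-only: every inheritance
   model compares all four genotypes, so a low-confidence call in any
   member makes the comparison meaningless. For the same reason missing
   genotypes are hard failures and are never imputed.
2. **Functional class.** Only protein-changing classes survive:
   `nonsynonymous`, `stopgain`, `stoploss`. Records with no annotation row
   are classed `unknown` and fail — the kept classes are an explicit
   allowlist, so anything uncharacterized is treated conservatively.
3. **Family-genotype discard rule.** A variant is removed when the proband
   is homozygous reference, when her genotype equals the unaffected
   sibling's, or when it equals *both* parents'. Genotype identity is
   unordered allele-multiset equality; a comparison involving missing data
   never asserts identity, and calls of different ploidy (a hemizygous male
   X call against a diploid call) are never identical.
4. **Inheritance models.** Surviving variants are classified under four
   models (next section); variants supporting none are dropped. Chromosome
   Y and MT variants support none of the four models and are set aside with
   a notice.
5. **Rarity.** Candidates must be rare in the reference population:
   `MAF < 0.01` (strict). A missing MAF means the variant is absent from
   the reference panel, which cannot exceed the threshold, so missing is
   treated as rare. For compound heterozygotes the rule is relaxed to the
   gene set: the whole set is kept when at least one member is rare. Rarity
   runs *after* model assignment precisely because of this model-dependent
   relaxation.
6. **Muscle-expressed genes.** Finally, candidates are restricted to a
   user-supplied list of genes mainly expressed in skeletal and cardiac
   muscle (exact, case-insensitive symbol match). No expression database is
   bundled: "mainly expressed" has no canonical threshold, so the list is
   an explicit input.

Because rarity and the gene restriction are both per-candidate predicates,
their relative order cannot change the final candidate set; it does change
the intermediate stage counts, which is why the order is fixed and recorded
in the run summary.

## The four inheritance models

With both parents unaffected, an inherited dominant allele is excluded by
the pedigree itself, so the dominant model reduces to **dominant de novo**:
proband heterozygous, all three relatives homozygous reference.

**Autosomal recessive**: proband homozygous alternate, both parents
heterozygous carriers, sibling anything but homozygous alternate.

**X-linked** branches on proband sex. For a female proband: proband and
mother heterozygous, father hemizygous reference, a male sibling hemizygous
reference (a female sibling must simply not be homozygous alternate — a
heterozygous sister would mirror the proband's genotype and is already
removed by the family rule; requiring more would contradict the carrier
mother's own unaffected status). For a male proband: hemizygous alternate
proband, carrier mother, hemizygous-reference father, and the same sibling
rule. All of chromosome X is treated as non-pseudoautosomal; male X calls
written diploid are normalized to hemizygous, and a heterozygous male X
call is flagged invalid-for-sex and treated as missing.

**Compound heterozygous** detection works without read-backed phase, which
family exomes rarely have. The parental origin of each proband-het variant
is inferred from the parents: unambiguously paternal when the father
carries the alternate and the mother is homozygous reference, and vice
versa. A variant carried by both parents is phase-ambiguous and can never
anchor a trans pair — this deliberately sacrifices sensitivity to avoid
false trans calls. A gene yields candidates only when it holds at least one
unambiguously paternal and one unambiguously maternal variant. One further
restriction is applied pairwise: a trans pair carried in full by the
unaffected sibling would make the sibling equally affected, so such pairs
are excluded. This extension follows from the sibling's health status
rather than from any single-site comparison (the family rule only blocks
identical single-site genotypes).

The classifiers are validated by exhaustive enumeration: all 81 autosomal
and all 36 chromosome-X quad genotype configurations are compared against
independently written truth predicates, and no configuration may satisfy
both the de novo and the recessive model.

## VCF normalization choices

Coordinates are VCF-native (1-based, fully closed) end to end.
Multiallelic sites are decomposed into one biallelic record per alternate
allele; genotypes are recoded so the chosen alternate becomes allele 1 and
alleles belonging to other alternates become *missing*, which conserves
each sample's alternate-allele mass across the decomposed records and
never fabricates a reference allele. Symbolic alleles and breakends are
skipped with a warning — the cascade targets SNVs and simple indels.
`"chr"` prefixes are stripped on both the VCF and the annotation table, so
mixed labeling cannot silently break the join.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_gq` | 50 | minimum Phred genotype quality, every member (boundary passes) |
| `min_dp` | 7  | minimum read depth, every member (boundary passes) |
| `max_maf` | 0.01 | strict upper bound on population MAF of the alternate allele |
| gene list | — | user-supplied muscle-expressed gene symbols |

The MAF is the frequency of the record's alternate (derived) allele as
annotated; no minor/major folding is applied. HGVS strings are carried as
opaque text and never parsed or validated.

## What the simulator emulates — and what it does not

`simulate_quad()` generates the statistical structure the cascade assumes:

* background sites with parental genotypes at Hardy–Weinberg equilibrium
  for a per-site MAF (drawn by default from a rare-skewed Beta(0.7, 6)
  truncated to [1e-4, 0.5] — a caricature of an exome's site frequency
  spectrum) and children produced by Mendelian transmission, including
  male X hemizygosity for the brother and the father;
* planted variants in the defining genotype configuration of each model,
  annotated `nonsynonymous` in distinct genes that appear on the emitted
  muscle-gene list (compound genes receive a rare member and a common one,
  so recovery exercises the at-least-one-rare rescue);
* genotyping error as a uniform redraw over the legal genotype space with
  probability ε per genotype — the redraw may restore the truth, so the
  realized discordance converges to 2ε/3 for diploid and ε/2 for
  hemizygous calls, and the statistical tests check against those
  *effective* rates;
* a two-level GQ caricature (99 when concordant, 30 when error-flagged —
  deliberately straddling the 50 cut), independent per-genotype
  missingness, and Poisson read depth with mean 46, a typical exome
  coverage for this study design.

Background sites each live in their own synthetic gene that is absent from
the emitted muscle-gene list, mirroring the real situation in which the
overwhelming majority of exome genes are not muscle-restricted; the final
filter therefore removes chance background configurations just as it does
in a real run. Sites are independent: there is no linkage disequilibrium,
no recombination map, and no read-level error model, so trans
configurations are planted explicitly rather than arising from haplotypes.
Passing recovery tests consequently demonstrate the correctness of the
cascade's logic under the stated statistical assumptions — they say
nothing about caller artifacts, batch effects, or annotation error in real
data.

Everything is deterministic given `seed`: identical parameters produce
byte-identical output files.

## The worked example

`make_worked_example()` writes a deterministic ten-record input set: the
five candidate variants of the motivating family — a de novo BAG3 missense
change absent from the reference panel, a three-variant NRAP compound
heterozygote (paternal rs200747403 at MAF 0.0004 rescuing maternal
rs2270182 and rs2275799 at MAF 0.25 and 0.27), and the X-linked FHL1
variant rs151315725 at MAF 0.0048 inherited from the carrier mother — plus
one decoy per stage, each violating exactly one rule. The unaffected
brother's genotypes at the candidate sites are set homozygous/hemizygous
reference: his individual genotypes are not part of the published record,
and this is the only configuration jointly consistent with the family
discard rule and his health status; it is an assumption of the fixture,
not a reported fact. Genomic positions other than the FHL1 site are
synthetic placeholders.

## Numerical and degenerate-input conventions

* Thresholds are inclusive boundaries (`GQ = 50`, `DP = 7` pass; `MAF =
  0.01` fails, being not strictly below).
* An empty VCF, or a run in which every record fails, is a success with an
  empty report (exit code 0 at the command line).
* Ties in report ordering cannot occur: rows sort by (chromosome rank,
  position, alternate allele), which is a total order on biallelic records.
* Report MAFs are printed in plain decimal notation with `.` for missing,
  so repeated runs are byte-comparable.

## Validation problem sizes

The shipped test suite enumerates all 117 classifier configurations
exhaustively; recovery is checked on 20 independently seeded simulations of
1,000 background sites with at least one planted variant per model
(sensitivity must be 1.0 and model-labeled false positives 0); the
Hardy–Weinberg and error-rate diagnostics use 10,000 sites with 3σ binomial
bounds. These sizes give the statistical checks enough resolution to catch
implementation errors while keeping the default suite fast.

## Known limitations

* Only the quad topology is supported — no extended pedigrees, half
  siblings or multiple families per file.
* Pseudoautosomal regions are not modeled; true PAR variants on X will be
  mis-normalized for males.
* Phase is inferred from parental genotypes only; a gene whose variants
  are all carried by both parents yields no compound-het call even if a
  true trans pair exists.
* Penetrance is assumed complete and sporadic phenocopies are not modeled;
  the X-linked model does not attempt to model X-inactivation skewing in
  carrier females.
* The cohort-scale properties of a real exome run (read counts, coverage
  profiles, caller-specific artifacts) are outside the simulator's scope.
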