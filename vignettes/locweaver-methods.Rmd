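---
title: "Methods: rule-based localization prediction in diderm bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based localization prediction in diderm bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`locweaver` treats subcellular localization in a gram-negative bacterium as
a classification over a fixed ten-label vocabulary: `CYT`, `IM`, `PERI`,
`OM`, `EXTRA`, the three lipoprotein anchorings `LIPO_IM` / `LIPO_OM` /
`LIPO_SURFACE`, `PHAGE` for bacteriophage structural proteins, and
`UNKNOWN`. The central assumption is the standard topogenesis model of
diderm bacteria: proteins leave the cytoplasm only through dedicated
machinery (Sec, Tat, holins, T1SS–T8SS), each of which imposes recognizable
constraints on its substrates — N-terminal signal peptides cleaved by signal
peptidase I or II, the twin-arginine motif, twin-glycine bacteriocin
leaders, a C-terminal &beta;-signal for Bam-assembled barrels, or (for T1SS)
no signal at all but a characteristic extracellular amino-acid composition.
Because each constraint is individually weak, the package's contribution is
the *integration*: a fixed-precedence decision tree over scanners, external
predictor votes, domain content and genome context, with an auditable trail
per call.

External predictors (SignalP/LipoP/TatP/TMHMM/Phobius/BOMP-style signal and
topology tools, PsortB/Cello/SosuiGramN/Subloc-style global predictors) are
*inputs*, supplied as tables; the package never re-implements their scoring.
The built-in scanners are deliberately simple fallbacks for when those
tables are absent, and external rows take precedence during integration.

## The scanners and their parameters

All positions are 1-based and inclusive; all scanners are pure functions
returning the leftmost qualifying match; the unknown residue `X` (internal
stop in a pseudogene translation) belongs to no residue class and can never
satisfy a motif. Residue sets are configuration, not code: the hydrophobic
set &phi; = {A, I, L, F, M, V, W} and hydrophilic set Z = {D, E, H, K, N, Q,
R, S, T} default to a conventional reading of those symbols and are
overridable (`motifs$phi`, `motifs$z`) because the symbols, not the sets,
are what the underlying biology fixes. The seven-residue "small" set
{A, S, G, C, T, P, V} is fixed by the specificity of methionine
aminopeptidase and is shared with the proteomics module.

* **Twin-arginine motif** `Z-X-R-R-X-phi-phi`, starting within
  `motifs$tat_window` = 35 residues. Some genuine Tat leaders are far longer
  (a ~68-residue hydrogenase leader is the classic example), so
  `motifs$long_leader = TRUE` extends the window to 80; the default stays at
  35 because a wide window on a genome scale mostly buys false positives.
* **Lipobox** `[LVIFMST][ASTVIG][GAS]C` with the Cys inside
  `motifs$lipobox_window` = 40. This is the community-consensus (DOLOP-style)
  regex; cleavage is reported before the Cys, which becomes +1 of the mature
  lipoprotein.
* **Tat lipoprotein**: both of the above, with the Cys at most
  `motifs$tat_lipo_max_gap` = 30 residues downstream of the RR pair. This
  composite exists because lipoprotein-aware tools do not model Tat leaders
  and Tat-aware tools do not model lipoboxes.
* **Sec/LepB heuristic**: one K/R in the first `sec_n_len` = 5 residues; a
  run of at least `sec_h_min` = 7 consecutive &phi; residues starting
  between positions 3 and 25; then the first Ala-X-Ala-style site whose −3
  position falls within `sec_c_window` = 12 residues of the h-region end,
  with the −3/−1 residues drawn from `motifs$cleav_set` = {A, S}. The
  restricted cleavage set is a deliberate design choice: with the full
  seven-residue small set the site search fires inside the h-region of
  classic leaders (e.g. the canonical MKKTAIAIAVALAGFATVAQA leader would
  cleave at 13 instead of the correct 21); Ala/Ser at −3/−1 reproduces the
  textbook site. The heuristic is a flagged fallback, not a SignalP
  replacement.
* **Twin-glycine leader**: a GG pair with the first Gly at positions 10–30,
  on ORFs of at most `gg_max_len` = 150 residues — bacteriocins are small
  and frequently missed by gene callers, which is why the locus-context
  search (`find_bacteriocin_candidates`) re-scans small ORFs near
  C39-peptidase T1SS loci.
* **&beta;-signal**: terminal Phe/Tyr and &phi; at 5, 7, 9 from the
  C-terminus. Proteins with large periplasmic C-terminal domains (TolC
  family) legitimately fail this test, which is one reason it only
  *supports* an OM call in the exported branch rather than gating it.
* **C-terminal PSSM**: log-odds over the last `pssm_L` = 10 residues with
  pseudocount `pssm_alpha` = 1 against proteome background frequencies;
  the decision threshold is the 5th percentile (`pssm_percentile`) of the
  training set's self-scores, i.e. a ~5% false-negative rate on the
  training material. Fixed windows (no gapped alignment of C-termini) keep
  the model training-set-size-robust; at least 20 training sequences are
  required.
* **Hydropathy spans**: 19-residue windows of mean Kyte–Doolittle
  hydropathy above 1.6, merged. Used only when no external topology table
  is present.

## The decision tree

`decide()` applies eight rules in fixed precedence; each fires only if no
earlier rule fixed the label, and the trail records every rule's outcome so
`replay_trail()` can audit any call against its record.

1. *Phage context* → `PHAGE`. Viral structural proteins are not cell
   components and would otherwise pollute the envelope classes.
2. *Secretion-machinery component* (registry domain hit) → the registry's
   curated component localization; `mixed` entries fall through.
3. *Lipoprotein signal* → sorting sub-rule. In the default `genus` mode the
   enterobacterial D+2 rule is **not** applied — the mode exists precisely
   because +2 composition fails to separate inner- from outer-membrane
   lipoproteins in at least some genera. Instead: a hit to an
   inner-membrane-anchor domain list (`decide$im_anchor_domains`, default
   the HlyD-family membrane-fusion domain pfam00529, whose lipoproteins are
   IM-anchored) gives `LIPO_IM`; Gly/Ser enrichment of at least
   `surface_threshold` = 0.05 over the proteome background gives
   `LIPO_SURFACE` (surface lipoproteins are Gly/Ser-enriched); otherwise
   `LIPO_OM`, the default fate of the Lol pathway. Setting
   `plus2_mode = "enterobacterial"` restores the classical D+2 rule.
4. *Twin-arginine (non-lipoprotein)* → the exported branch. Tat substrates
   are typically periplasmic redox proteins; no OM override is applied
   without independent &beta;-barrel evidence.
5. *Transmembrane spans*: a single N-terminal span coinciding with a
   predicted signal peptide is discounted (topology tools notoriously count
   signal peptides as spans); two or more remaining spans → `IM`; exactly
   one N-terminal span is treated as a signal only when an SP-aware tool
   (`decide$sp_aware_tools`, default `phobius`) independently calls a
   signal, otherwise the protein is membrane-anchored.
6. *Sec signal* → the exported branch.
7. *Exported branch*: any &beta;-barrel evidence (external barrel call, the
   C-terminal signature, a PSSM score above threshold, or an OM-informative
   domain) → `OM`; otherwise a majority vote over global predictors
   restricted to {`PERI`, `EXTRA`, `OM`}; an abstaining vote defaults to
   `PERI` — the most common exported fate — at low confidence, flagged
   `defaulted`.
8. *No signal, no anchor*: a location-informative domain, if one is mapped;
   otherwise a majority vote over all global predictors; abstain defaults to
   `CYT`, low confidence, flagged `defaulted`.

Votes are weighted (`decide$weights`, default all 1.0 — the package takes no
position on relative tool reliability) and ties abstain rather than guess.
Confidence counts concordant independent evidence sources: `high` at three
or more, `medium` at two, `low` otherwise.

**Domain-map refinement.** `infer_domain_locations()` maps an accession to a
location when at least `domains$min_n` = 5 carriers agree with purity
`domains$purity_min` = 1.0. Calls produced by an abstain default are
excluded from the inference. This exclusion is a considered deviation from
"use all calls": a default is not a prediction, and including defaulted
carriers makes the refinement unreachable at purity 1.0 — the very proteins
one wants to refine (evidence-free carriers, defaulted to `CYT`) would
dilute their own domain's purity below threshold. With the exclusion, the
second pass promotes them and is provably a fixed point of further passes.

**Tree topology.** The published narrative of this curation strategy fixes
the *order of concerns* (machinery first, then rare signals, then
spans-vs-signals, then the common Sec route, with domains and votes
throughout) but not every branch. The precedence above is this package's
reference interpretation of that narrative; it is centralized in one
function and documented here so a different reading is a one-place change.

## Cross-genome reconciliation and proteomics

A group verdict is `consistent` / `mixed` / `no_evidence` over evaluable
members (pseudogenes excluded by default; `orthocheck$exclude_pseudogenes`).
Anomaly flags encode the two classic gene-model failure modes: a member
whose length deviates more than `len_frac` = 0.2 from the group median
(wrong start/stop), and a member missing a signal that at least
`sp_frac` = 0.75 of its orthologs carry (displaced 5' end or a leader too
long for the scanner window).

Tryptic peptides validate N-termini: trypsin cuts after K/R, so a peptide
whose N-side is nonspecific witnesses in-vivo processing — but such peptides
also arise from sample handling, so only the partial-N peptide mapping
*most closely* to the N-terminus counts, with ties broken by observation
count then length, and ambiguous multi-site peptides discarded. Start
position 2 after an initiator Met is attributed to methionine
aminopeptidase (next residue small) or aminopeptidase P (next residue Pro);
other starts must match a predicted cleavage site exactly
(`proteoval$cleavage_tol` = 0; the optional no-cut-before-Pro trypsin
refinement is off by default since observed digests do produce such
peptides).

## What the synthetic generator emulates — and what it does not

`synth_bundle()` emits a 19-genome panel (50 proteins each by default) with
a fixed per-genome slot layout rather than stochastic per-class rates: every
scanner, locus type, decision branch, decoy and digest event is planted
exactly once per genome, which makes end-to-end recovery a sharp 100%-or-bug
statement instead of a sampling estimate. Sequences are drawn i.i.d. from a
uniform (or optionally genus-like) composition and *resampled until the
scanners report exactly the planted motif set*, so background sequence can
never accidentally carry a signal; decoys are near-misses violating exactly
one clause (lipobox Cys→Ser, RR→RK, GG→GA, terminal Phe→Lys), so each rule
clause is independently exercised. Tool tables are derived from truth with
configurable dropout and label noise, and reproduce the real tools' known
blind spots: the lipoprotein caller skips Tat lipoproteins, the Tat caller
skips lipoproteins, topology tools report a spurious 1–21 span over signal
peptides, and the mixed-evidence type-V slot gets the characteristic
OM-versus-extracellular split.

Passing on these fixtures therefore demonstrates that the *integration
logic* is correct under its own assumptions. It does **not** demonstrate
performance on real proteomes: real sequences violate the i.i.d. background
(signal-like subsequences occur by descent, not chance), real tool errors
are correlated rather than independent, real leaders vary in length and
composition, and real gene models are wrong in ways the generator only
caricatures. The generator also makes no attempt to model domain-architecture
evolution or mass-spectrometry noise.

`synth_curation_panel()` is a separate, explicitly synthetic stand-in for a
genus-scale curated ortholog/localization table: its core-group count and
curated per-location tallies are *inputs*, so round-tripping it through the
writers, parsers and `core_groups()` validates the bookkeeping machinery,
not an external dataset.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive everywhere, including every writer.
Sequences shorter than a motif return no match, never an error; a mature
lipoprotein of length 1 has no +2 residue and sorts `OM` with a warning.
Locus clustering measures gaps in intervening genes
(`sysfinder$max_gap_genes` = 3) because physical base-pair distances vary
with gene density; clustering is normalized by coordinate sort, so input
order never matters. Vote ties abstain (policy `abstain`); the `alpha`
policy exists for users who prefer a deterministic label over `UNKNOWN`.
All randomness in the generator flows from one integer seed with fixed
per-table offsets, making every table independently byte-reproducible.

Problem sizes used by the test suite — a 10,000-sequence scanner corpus, a
10,000-record decision-tree property set, the 950-protein bundle and
exhaustive substring enumeration on short parents — were chosen as the
smallest sizes at which every rule clause and branch is exercised many times
over; all are fixed-seed and rerun identically everywhere.

## Known limitations

* The Sec heuristic is a fallback; genuine SignalP-class accuracy requires
  supplying external predictions.
* Phage loci are taken from input annotation; there is no de novo prophage
  finder, and only holin refinement is computed within them.
* Ortholog groups are inputs; the package reconciles but never infers them,
  and anomalies are reported, never auto-fixed.
* Tat "hitchhikers" (signal-less partners co-exported in complexes) are
  listed for review by `tat_hitchhiker_report()`, never auto-called.
* The five-gene amyloid-fiber-type loci that historically required manual
  literature review are out of rule-based reach by design.
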