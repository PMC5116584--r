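---
title: "Modelling repressor-controlled RCA logic gates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling repressor-controlled RCA logic gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcalogic)
```

## The system being modelled

Rolling circle amplification (RCA) uses a strand-displacing polymerase
(phi29-type) that travels around a circular single-stranded template
indefinitely, producing a long tandem-repeat product whose accumulation is
followed in real time with an intercalating dye. A transcriptional
repressor bound to its operator sequence on the circle is a physical
roadblock: because the polymerase must traverse the *whole* circle on every
revolution, one bound site anywhere suffices to stop amplification.

Allosteric regulation supplies the switching logic. Inducer-regulated
repressors (LacI, GalR) bind DNA by default and are released by their
inducer (IPTG, D-galactose). Anti-inducer-regulated repressors (TrpR,
MetJ) bind only in the presence of their co-repressor (L-tryptophan,
S-adenosylmethionine). Taking the metabolite and the repressor protein as
the two inputs of one module and RCA signal as output, an inducer-type
module computes `m ∨ ¬r` (an ORN gate) and an anti-inducer-type module
computes `¬(m ∧ r)` (a NAND gate).

Two composition rules follow directly from the geometry:

* **series** — several operators on one circle: the template runs only if
  *every* site is free (conjunction);
* **parallel** — several distinct circles in one tube: signal appears if
  *any* template runs (disjunction).

`rcalogic` implements this as four layers — Boolean binding rules, a
propositional-calculus mirror, a truth-table-to-design compiler, and a
kinetic/quantification layer — kept deliberately separate so that the
logic layer stays exact and exhaustively testable.

## Binding rules and their assumptions

Binding is modelled as a threshold Boolean rule, not equilibrium
occupancy. A site is occupied iff its cognate repressor protein is present
and, for inducer-type repressors, *no* ligand reaches its switching
threshold for that repressor — respectively, for anti-inducer-type
repressors, *some* ligand does. The experiments this emulates report clean
on/off behaviour at fixed working concentrations, so a graded occupancy
model would add parameters that nothing in the data constrains; the
threshold rule keeps every higher layer exact. (A Hill-type occupancy
extension would slot in behind `site_occupied()` without touching any
interface, but is deliberately not part of the model.)

Cross-reactivity is encoded in the same thresholds. Each repressor carries
a map ligand → minimal switching concentration (mM); non-cognate entries
express the observed high-concentration cross-talk:

| ligand | cognate target (threshold) | cross target (threshold) | working conc. |
|--------|---------------------------|--------------------------|---------------|
| IPTG   | LacI (0.1 mM)             | —                        | 5 mM |
| D-Gal  | GalR (0.1 mM)             | LacI (10 mM)             | 5 mM |
| L-Trp  | TrpR (0.1 mM)             | —                        | 1 mM |
| SAM    | MetJ (0.1 mM)             | TrpR (1.5 mM)            | 1 mM |

The working concentrations of D-Gal and SAM sit below their cross
thresholds by design, which is exactly the orthogonality condition: at
working concentrations the 4×4 `switch_matrix()` is diagonal, and raising
D-Gal or SAM above threshold flips the LacI or TrpR column. The cognate
thresholds (0.1 mM) and the IPTG/L-Trp working concentrations (5 mM and
1 mM) are package defaults chosen as typical sensitivities for these
systems — the source experiments do not print them for the RCA reactions —
and all of them are ordinary registry data that a user can replace.

MetJ represses detectably but imperfectly; it carries a `leak` of 0.15
(fraction of full polymerase rate escaping a bound site). Leak affects
only the kinetic layer; the Boolean layer treats MetJ repression as
effective, matching the printed truth tables. Repressor and template
amounts (the experiments use ≥100-fold repressor excess over 0.05 pmol of
template) are assumed saturating and are not modelled.

## The gate catalogue

`paper_design()` returns the 17 published constructs as *data* — templates,
constant species, input mappings — not as special-cased code:
four basic modules, the series/parallel combinations (AND, OR, NOR, NAND,
ANDN, ORN), the composite-input gates (XNOR, XOR), the single-repressor
reductions (YES, NOT, ALL, NONE) and the three-input series gate
(LacI+GalR+TrpR, active only for IPTG ∧ D-Gal ∧ ¬L-Trp).

Gate classification canonicalizes over input permutations, so the
asymmetric gates (ANDN, ORN, YES, NOT) absorb their mirror images and the
16 two-input Boolean functions collapse onto exactly 12 names — the
catalogue's own count. The YES and NOT designs read out their *second*
input (D-Gal resp. L-Trp); `catalogue_truth_table()` therefore stores their
design-oriented columns and classification recovers the canonical names via
the permutation.

## Propositional derivation

`derive()` searches compositions of the four basic modules for a formula
equivalent to a target truth table, using the three operations that have a
physical counterpart: SUBSTITUTE (instantiate a module's atoms), SERIES_AND
and PARALLEL_OR. Cost counts composition steps (the constructed gates all
need ≤ 3; the default bound is 4). The search is a deterministic
breadth-first closure over semantic equivalence classes: at most
`2^(2^n)` distinct output columns exist, so the state space is tiny and
ties are broken by (fewer implied templates, enumeration order: basis
order, then substitution order) for reproducible traces.

One design choice is worth spelling out. Substitution replaces a module's
*metabolite* atom with an input variable or a constant (`T` = always
supplied, `F` = never supplied), but by default replaces the *repressor*
atom only with `T`/`F`. This mirrors designs whose input signals are
metabolite additions, and it gives the two module families distinct
algebraic roles: inducer-type modules contribute positive literals
(`ORN(A, T) = A`), anti-inducer-type modules negative ones
(`NAND(A, T) = ¬A`). Under this rule the inducer-only basis generates only
monotone functions — so NOR is provably out of its reach, which the test
suite checks by exhaustive search — while the full basis reaches all 13
constructed gates. Some published designs do switch repressor *proteins*
as inputs (XNOR's composite inputs, NONE's LacI input);
`repressor_substitution = "full"` widens the rule accordingly, at the cost
of the monotonicity structure.

`trace_to_system()` maps a found derivation back onto chemistry: every
distinct substituted module instance is realized by a distinct repressor of
the matching mode (so a formula reusing "the" ORN module twice with
different inputs is realized by LacI *and* GalR), series steps co-locate
sites on one template, parallel steps separate templates. The round trip —
derivation → reaction system → truth table — is property-tested for all 13
gates.

## Compilation

`synthesize()` performs exact two-level minimization: Quine–McCluskey prime
implicants plus an exhaustive minimal cover, which is trivial at n ≤ 4 and
makes designs reproducible (ties among equal-cost covers are broken
lexicographically on the implicants' minterm bitmasks). Each implicant
becomes one template; a positive literal becomes an inducer-type site whose
repressor is constant and whose inducer rides on the input; a negative
literal becomes an anti-inducer-type site. Constant-true targets get a
site-free template; constant-false targets a constantly bound
inducer-type repressor whose inducer is never supplied (the NONE-style
encoding). Inputs in synthesized designs carry metabolite sets only;
protein-carrying inputs remain available in hand-written designs. With the
default 2+2 repressor library this makes every two-input function feasible,
while three-input functions needing three like-polarity literals correctly
report the missing polarity.

## Kinetics and RRR quantification

The simulator doubles as the package's synthetic-data generator. A curve
is piecewise linear with additive noise:

```
value(t) = min(plateau, baseline + rate · max(0, t − lag) + ε),
rate     = k_full · min(capacity, Σ_templates f_i),
f_i      = 1 (active template) or max leak over its occupied sites,
ε        ~ N(0, noise_sd²) i.i.d.
```

Defaults: `baseline_rfu` 100, `k_full` 10 RFU/min, `duration` 15 min
sampled every 0.5 min (31 points, matching a ~15-min plate-reader run),
`lag` 1 min, `noise_sd` 0.05·k_full, `plateau_rfu` 400, `capacity` 1.
The real curves are shown only as figures, so these are synthetic
calibrations chosen to look like a routine SYBR-based RCA run, not fits.

`capacity` deserves its own paragraph. If template contributions added
without bound, a parallel gate with one of two templates running would
reach exactly half the rate of its both-running condition, and the 0.5
threshold would misread the published OR gate. The published data show the
opposite: one running template already produces a full-scale signal,
i.e. the reaction is polymerase/primer/dye-limited. The simulator therefore
caps the summed template activity at `capacity` template equivalents
(default 1); below the cap, parallel templates still contribute
additively. Setting `capacity = Inf` recovers the purely additive model.

`estimate_rate()` implements slope-of-the-linear-part: ordinary least
squares over every contiguous window spanning ≥ 40% of the samples, keeping
windows with R² ≥ 0.9 and returning the steepest — this automatically
excludes the lag and the plateau, which bend the fit. For flat (fully
repressed) curves no window reaches the floor and the best-fitting window
is used, yielding a near-zero slope. The estimator is deterministic given
the curve and is exact on noise-free lines.

`quantify_experiment()` simulates all `2^n` conditions **plus a
repressor-free control**, normalizes every slope to the maximum across all
of them (RRR, clamped to [0, 1]), and binarizes at RRR > 0.5. The control
is what keeps normalization well-defined for gates whose every condition is
repressed (NOT, NONE): their RRR then sits at the leak level, far below
threshold. An RRR of exactly 0.5 reads as 0 — the published rule defines
only "above → 1" and "below → 0", and requiring strict excess is the
conservative completion.

What passing the kinetic tests shows — and what it does not: the noise-free
pipeline reproducing the Boolean layer, and ≥ 99% table recovery over 1000
seeded runs per gate at default noise, demonstrate that the quantification
pipeline is self-consistent and robust to instrument-like noise. They say
nothing about real enzyme kinetics (no mechanistic polymerase model, no
enzyme-level stochasticity, no fitting to measured fluorescence), and the
RRR magnitudes for leaky conditions are properties of the chosen leak
value, not measurements.

## Sequence layer

`assemble_template()` lays out the circularizable, 5′-phosphorylated
strand linearized at the ligation junction: an 18-nt primer-binding
region, then each operator preceded by a 6-nt spacer in the circular site
order, then deterministic 50% GC padding to the target length. The splint
is the reverse complement of the head-to-tail junction (9 nt on each
side); the primer is the reverse complement of the primer-binding region.
Coordinates are 0-based half-open on the linearized strand.

`scan_operators()` screens for unintended operator occurrences by exact
matching over the doubled sequence (so junction-spanning hits are found),
on both strands — repressors read the double-stranded motif and the
orientation of an embedded operator is not constrained by the model — with
palindromic motifs counted once. Scanning is invariant under rotation of
the linearization point, and every assembled build must scan clean against
the whole operator database.

The shipped operator motifs (`lacO1_syn`, `galO_syn`, `trpO_syn`,
`metbox_syn`) are synthetic placeholders modelled on the canonical
literature motifs and are flagged `synthetic=true` in FASTA headers; real
designs should load the experimentally used sequences into
`operator_db()`. Secondary structure, melting temperature and ligase
fidelity are out of scope.

## Numerical and testing choices

* Truth-table rows are in canonical binary order, first input most
  significant; all layers share `assignment_rows()` so orderings cannot
  drift apart.
* All randomness flows through explicit integer seeds; multi-condition
  runs derive per-condition seeds as `seed·1000 + i` (kept below 2³¹).
* Exhaustive checks are used wherever the space is small: template
  activity versus site conjunction over all ≤ 3-site × species subsets,
  equivalence over ≤ 10 atoms, covers versus a brute-force minimal-DNF
  oracle for n ≤ 3, all 16 two-input syntheses.
* Problem sizes in the test suite: 1000 seeded quantification runs per
  catalogue gate for the noise-robustness property, 200 seeded curves for
  the slope-estimator accuracy check, 30 random three-input targets for
  compiler soundness. These sizes give stable pass/fail behaviour at the
  default noise level.

## Known limitations

* The Boolean layer has no notion of partial repression; leak exists only
  kinetically.
* No layered/cascaded circuits: the output of a gate is fluorescence, not
  a species another gate could consume, so composition stops at one level —
  as in the underlying platform.
* Kinetic parameters are synthetic calibrations; reanalysis of real data is
  supported only through `read_curves()` + `estimate_rate()` on exported
  plate-reader tables.
* The compiler restricts synthesized inputs to metabolite sets; designs
  with protein-carrying inputs must be written by hand (or derived with
  `repressor_substitution = "full"` and realized via `trace_to_system()`).
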