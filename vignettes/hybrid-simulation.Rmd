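---
title: "Hybrid deterministic-stochastic simulation of tabular reaction-network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid deterministic-stochastic simulation of tabular reaction-network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsim)
```

## The model

`netsim` treats a single cell as two coupled sub-models.

**Signalling (deterministic).**  Proteins, complexes and modified species
evolve by mass-action and formula rate laws in nM and seconds.  Every
species and every reaction has a *home compartment*; concentrations are
always expressed relative to the species' own compartment volume.  A rate
law evaluates in the reaction's compartment, so a reactant living elsewhere
enters a mass-action law as $c_i \, V_{\mathrm{home}(i)}/V_{\mathrm{rxn}}$
(a receptor at cytoplasmic concentration entering an extracellular binding
step is multiplied by $V_c/V_e$), and the derivative contribution of
reaction $j$ to species $i$ is

$$\frac{dc_i}{dt} \mathrel{+}= S_{ij}\, v_j \, \frac{V_{\mathrm{rxn}(j)}}{V_{\mathrm{home}(i)}},$$

which keeps every state variable in home-compartment nM and conserves
molecule numbers across compartments.  Mass-action reactant exponents equal
the absolute stoichiometric coefficient (a coefficient of $-2$ squares the
term); a coefficient-free mass-action cell is a zeroth-order source.
Formula laws are taken verbatim — any volume correction inside a user
formula is the author's responsibility, because the package cannot know
which symbols in an arbitrary expression denote cross-compartment
reactants.  The formula grammar is deliberately small (`+ - * / ^`,
parentheses, symbols, numbers): it covers Michaelis–Menten and Hill-style
kinetics while staying auditable and mapping one-to-one onto SBML MathML.

**Gene expression (stochastic).**  Each gene is a telegraph unit: every
copy switches on and off with rates $k_{\mathrm{on}}$ (activation) and
$k_{\mathrm{off}}$ (inactivation), and active copies transcribe.  Over one
exchange window of length $\Delta t$ the copy's end state is drawn from the
exact two-state propagator,

$$P(\mathrm{off}\to\mathrm{on}) = f\,(1 - e^{-(k_{\mathrm{on}}+k_{\mathrm{off}})\Delta t}), \qquad
  P(\mathrm{on}\to\mathrm{off}) = (1-f)\,(1 - e^{-(k_{\mathrm{on}}+k_{\mathrm{off}})\Delta t}),$$

with $f = k_{\mathrm{on}}/(k_{\mathrm{on}}+k_{\mathrm{off}})$.  We chose
end-state sampling over the more obvious per-event leap
$P = 1 - e^{-k\Delta t}$ because the latter's discrete-chain occupancy is
$(1-e^{-k_{\mathrm{on}}\Delta t})/\big((1-e^{-k_{\mathrm{on}}\Delta t}) +
(1-e^{-k_{\mathrm{off}}\Delta t})\big)$, which at a 30 s window and
asymmetric rates deviates measurably (several percent) from the telegraph
stationary occupancy $f$; the exact propagator preserves $f$ for any window
length and any rate asymmetry, and reduces to the same limits (no switching
when a rate is zero, $1/2$ for symmetric rates).  mRNA counts follow
tau-leaping with rates frozen at the window start: births
$\sim \mathrm{Poisson}(n_{\mathrm{active}}\, k_{\mathrm{tc}}\, \Delta t)$,
deaths $\sim \mathrm{Poisson}(k_{\mathrm{deg}}\, m\, \Delta t)$ truncated
at the current count so counts never go negative.  Because the birth–death
recursion is linear, its stationary mean is exactly
$n\, f\, k_{\mathrm{tc}}/k_{\mathrm{deg}}$ despite the approximation; the
truncation bias is negligible whenever $k_{\mathrm{deg}}\Delta t \ll 1$,
which holds for physiological mRNA half-lives at a 30 s window.

Transcription is regulated through per-gene Hill entries.  Activators
combine as a saturating OR-gate and repressors multiply:

$$u = \frac{\sum_a (x_a/B_a)^{A_a}}{1 + \sum_a (x_a/B_a)^{A_a}}, \qquad
  w = \prod_r \frac{1}{1 + (x_r/B_r)^{A_r}}, \qquad
  k_{\mathrm{tc}} = (k_{\mathrm{const}} + k_{\mathrm{max}}\, u)\, w.$$

The input format names the constitutive and maximal rate constants but not
their composition law; this form reduces to $k_{\mathrm{const}}$ with no
regulators, saturates at $k_{\mathrm{const}} + k_{\mathrm{max}}$, and makes
independent repressors multiplicative.  Regulator concentrations are read
at the window start; regulation acts on transcription only (the switching
rates stay constant), because the regulation table parameterizes nothing
else.

**Coupling.**  Every 30 simulated seconds the ODE state is handed to the
gene-expression module, which returns new mRNA counts; transcript species
(identified by the `m_<gene>` naming convention, configurable) are
overwritten with the counts converted to nM via the transcript's home
compartment volume, $c = m/(N_A V)\times 10^9$.  Translation rate laws read
those transcript species, closing the loop.  In deterministic mode no
sampling occurs: transcripts follow the expected-value update
$m \leftarrow m + \Delta t\,(n f k_{\mathrm{tc}} - k_{\mathrm{deg}} m)$ on
the same grid, structurally symmetric with the hybrid path, so a
deterministic run is the average-cell limit — a property the test suite
checks quantitatively by scaling gene copy numbers up while scaling
per-copy transcription down.

## Parameters that matter

| Parameter | Units | Default | Why |
| --- | --- | --- | --- |
| `exchange_s` | s | 30 | module exchange interval; the grid on which transcripts update |
| `rtol`, `atol` | –, nM | 1e-6, 1e-9 | lsoda tolerances; halving them moves final states by far less than reporting precision |
| `clamp_tol` | nM | 1e-6 | concentrations in $(-\texttt{clamp\_tol}, 0)$ after a window are clamped to 0 (stiff-solver noise); larger negatives abort, since they indicate genuine model error |
| `sphase_threshold` | nM | 20 | summed Cyclin E+A+B above this (strictly) marks S-phase entry |
| death criterion | – | cPARP > PARP | strict inequality; equality is still alive |
| calibration `tol` | relative | 0.01 | per-gene total-protein tolerance of the translation fit |
| `max_iter` | – | 25 | calibration cap; the proportional update is exact in one step for linear chains |
| `log10_halfwidth`, `n_grid` | log10, – | 2, 25 | coordinate-fit search range and resolution per parameter |

## Initialization

Targets come from proteomics where available (`protein_mpc`, converted to
reference-compartment nM) and otherwise from mRNA times a gene-level
protein/mRNA ratio.  The calibrator then alternates: simulate to the
unstimulated steady state, compute each gene's volume-corrected total over
all species carrying its identifier (transcripts excluded), and multiply
the gene's translation rate constant by target/current.  For a linear
production–decay chain the first update lands exactly on the closed form
$k_{\mathrm{TL}} = k_{\mathrm{deg},P}\, P_{\mathrm{target}}/m^\ast$, and a
re-run changes nothing (a fixpoint); for complexes the iteration converges
geometrically.

One numerical choice deserves note: at the deterministic unstimulated
stationary point the expected mRNA is the constant
$n f k_{\mathrm{tc}}/k_{\mathrm{deg}}$, so the steady-state solver pins
transcripts at that value and integrates the signalling ODEs directly over
a long horizon (1000 simulated hours, with a scaled-derivative stationarity
check) instead of stepping the 30 s exchange grid two hundred thousand
times.  At stationarity the two procedures are mathematically identical;
the direct integration is orders of magnitude cheaper.

The starved-cell phenotype check runs a ligand-free deterministic
simulation over a 48 h horizon (configurable) and reports death or S-phase
violations with their times; criteria whose role species are not mapped
pass vacuously, with a notice.  Single-parameter scans evaluate a
trajectory predicate on a log-uniform grid and select the smallest passing
value (the format gives a range but no selection rule; smallest-passing is
deterministic and conservative).  Coordinate-wise fitting searches
$\pm 2$ log10 around each parameter in turn, keeping the best value; the
current value always lies on the (odd-sized) grid, so the SSE is monotone
non-increasing across steps, and ties break toward the current value.

## The fixture generator, and what passing tests do not show

`toy_spec()`/`make_toy_model()` emit complete input sets in the exact TSV
dialects: telegraph genes with translation and first-order protein decay,
optional Michaelis–Menten signal production (so both compiler branches are
always exercised), an optional extracellular-ligand/cytoplasmic-receptor
binding pair spanning compartments, a tunable PARP/cleaved-PARP pair and a
tunable cyclin triple for the phenotype criteria, and arbitrary Hill
regulation edges.  The four compartments mirror a mammalian cell's volume
hierarchy (cytoplasm 5.25e-12 L, nucleus 1.75e-12 L, mitochondria
3.68e-13 L, extracellular 1e-10 L) so volume-correction code paths carry
realistic ratios.  Default sampling ranges are chosen to be physiological:
switching rates 1e-3–5e-3 /s, per-copy transcription 0.05–0.2 molecules/s,
mRNA degradation 2e-4–1e-3 /s (half-lives of tens of minutes to an hour),
protein abundances 1e4–1e5 molecules per cell, protein half-lives 1–10 h;
`rate_ranges` can pin any of them.  `analytic_reference()` returns the
closed forms (stationary active fraction, mean mRNA, steady-state protein)
for the linear motifs, and flags regulated genes as outside the analytic
family.

These toys are *linear* in the coupling between expression and signalling:
mean behaviour equals deterministic behaviour exactly, which is what makes
them sharp oracles.  Real networks are nonlinear, so hybrid population
means need not track the deterministic trajectory there, stochastic
fluctuations can shift mean phenotypes, and a passing law-of-large-numbers
test says nothing about the size of such effects in a real model.
Likewise, the generator makes no attempt to resemble the biology of a
full-scale signalling network — it exercises the machinery, not the
biology.

Two test-design choices are worth recording.  For the stationary-moment
checks, time averages are autocorrelated, so standard errors come from
batch means (25–40 batches after burn-in) rather than the naive i.i.d.
formula.  For the law-of-large-numbers study, the transcript must actually
mix within the simulated horizon: the study pins
$k_{\mathrm{deg}} = 10^{-3}$ /s (relaxation time $\approx$ 17 min) and runs
1.5 h ($\approx 5.4$ relaxation times) with 200 cells at copy-number scales
1 and 25 — with the package's slower default turnover ranges, a short
horizon measures only initial-sampling noise and the scale contrast
drowns.

## Numerical and format choices

* **Integrator.**  `deSolve::lsoda`, switching automatically between stiff
  and non-stiff methods, with the tolerances above.  Integration failure
  aborts with the simulated time stamp.
* **TSV dialects.**  Strict tab separation, `.` decimals, one header row
  per file.  Numbers are written with the shortest decimal representation
  that round-trips the double exactly, so write-then-read is the identity.
  Missing proteomics/half-life cells are empty strings and parse to `NA` —
  never zero, since zero is a legal rate.  Malformed cells fail with the
  file, row and column named; nothing is silently coerced.
* **Validation order-sensitivity.**  Species rows must match the
  stoichiometric matrix rows *in order*, and reaction rows its columns;
  the regulation table's rows must follow the omics gene order.  Permuting
  any of these is an error, not a reinterpretation.
* **SBML.**  Level 3 Version 2 core, written and read with `xml2`.
  Compartment GO terms and species gene identifiers travel as RDF
  (biology-qualifier) annotations; each global parameter records its source
  reaction and original local name in an annotation; each reaction stores
  its home compartment in the L3 `compartment` attribute and its complete
  rate law (volume-correction factors already folded in) as MathML, so an
  import reproduces the right-hand side bit-for-bit and a second export is
  byte-identical.  Identifiers are sanitized deterministically with an
  emitted translation table.  Events, assignment rules and algebraic rules
  are not used.  The gene-expression bundle and observables are not part of
  SBML and come back empty on import; a re-imported model supports
  deterministic signalling simulation and RHS evaluation, while hybrid
  simulation starts from the TSV inputs.
* **Parameter naming.**  Globals are assigned in rate-law order:
  `k<j>` for reaction *j*'s mass-action constant, `k<j>_<i>` for its *i*-th
  formula parameter — a bijection from (reaction, local name) pairs, stable
  across recompiles.
* **Seeds.**  Hybrid runs are bit-reproducible given a seed; deterministic
  runs ignore the seed entirely.  Sweeps derive per-cell seeds as
  `base_seed + (condition-1)*num_cells + cell`, which is reproducible,
  collision-free and independent of worker count or execution order, so a
  population result never depends on parallelism.
* **Fate precedence.**  A dead cell is excluded from the S-phase count —
  a cell cannot be both dead and cycling; the criteria themselves do not
  state a precedence.
* **Observable reference volume.**  Volume-corrected observables and gene
  totals are normalized to the cytoplasm volume (configurable): it is the
  natural common denominator when most protein mass is cytoplasmic.

## Known limitations

* No cell division or lineage tracking, and no spatial or cell–cell
  coupling: each simulated cell is an independent well-mixed compartment
  system.
* Regulation of mRNA *stability* (protein-dependent degradation rates) is
  not modelled; the regulation table parameterizes transcription only.
* The alternate rate-law dialect that dispenses with the stoichiometric
  matrix is not implemented; the matrix is the single source of reaction
  topology.
* Merging two model input sets is deliberately out of scope — name
  collisions and duplicated reactions need human judgement.
* SBML import targets documents this package wrote.  The reader handles
  core L3 constructs (species, compartments, parameters, reactions,
  MathML kinetic laws) but not events, rules, function definitions or
  units machinery from arbitrary third-party files.
* Within a window the ODE sees frozen mRNA and the gene module sees frozen
  protein; both approximations are first-order in the exchange interval.
  The 30 s default is far below the timescales of transcription,
  translation and degradation, where the coupling error is negligible.
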