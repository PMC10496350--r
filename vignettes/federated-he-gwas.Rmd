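---
title: "Threshold homomorphic encryption and federated score-test GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold homomorphic encryption and federated score-test GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedhegwas)
```

## The problem

Several hospitals or biobanks each hold genotype dosages $G_s$
($N_s \times M$), covariates $X_s$ ($N_s \times p$) and a binary phenotype
$y_s$ for their own subjects and want a joint genome-wide association study
without moving individual-level data. `fedhegwas` implements the
collaborative route: all quantities that leave a site are either encrypted
under a *threshold* CKKS-style homomorphic scheme — one public key, a secret
key additively shared across sites so that no party can decrypt alone — or
masked with collective random noise before a joint (collective) decryption.
On top of the encrypted matrix toolbox sit a federated logistic-regression
null model, a GMMAT-style score test for each variant, and a secure
meta-analysis that needs only per-site summary statistics.

## The threshold scheme

**Keys.** The master secret key $msk$ is a ternary polynomial of degree
$n$. A key-generation role (run once, offline) splits it into $S$ additive
shares: per coefficient, every non-final site receives rounded Gaussian
noise with variance $2^{\lambda_{dsk}}$ (default $\lambda_{dsk} = 20$), a
randomly chosen site additionally receives the master coefficient, and the
final site receives the modular complement, so the shares sum to $msk$
coefficient-wise mod $q$. The public key is
$(pk_0, pk_1) = (-a \cdot msk + e,\, a)$ with $a$ uniform and $e$ a small
Gaussian. Each share travels in the key bundle sealed with authenticated
symmetric encryption under a key derived from the site's passphrase; a
shared 256-bit symmetric key protects partial decryptions in transit. The
AEAD is built from the package's own SHA-256 primitive (counter-mode
keystream, encrypt-then-MAC HMAC tag).

**Collective decryption.** For a ciphertext $(c_0, c_1)$, site $s$ computes
the partial decryption $c_1 \cdot dsk_s + e_{sm}$, where the *smudging*
noise $e_{sm}$ has variance $2^{smudging\_bits}$ (default 40 bits) and
statistically hides the key share; exactly one site (lowest id, by
convention) adds $c_0$. Summing all partials mod $q$, center-lifting and
decoding recovers the plaintext up to smudging and encoding noise. At the
slot layer the smudging contributes an error of roughly
$\sqrt{n\,S/2}\; 2^{smudging\_bits/2} / \Delta$ for encoding scale
$\Delta$: with the defaults ($n = 16384$, $\Delta = 2^{30}$, 40-bit
smudging) this is a few times $10^{-3}$ on fresh ciphertexts, and it decays
as the scale grows under multiplication because the noise lives at the ring
layer. This scale-dependence matters: the IRLS weight updates are decrypted
at grown scales and converge below $10^{-4}$ only because the smudging
error shrinks accordingly.

**Two backends, one contract.** `backend = "toy_ckks"` is a real
single-modulus RLWE/CKKS implementation at small ring degree: inverse
canonical-embedding encoding (slots ordered along the orbit of 5 so Galois
automorphisms rotate slots), randomized RLWE public-key encryption,
relinearization and per-power-of-two rotation keys via digit-decomposed
key switching (8-bit digits), and exact negacyclic arithmetic through
number-theoretic transforms. The modulus is a product of one or two
NTT-friendly primes below $2^{50}$, so residues stay exact in doubles and
products fit 128-bit integers; the composite $q$ (up to 100 bits) is a
single logical modulus — there is no residue-number-system modulus chain,
and rescaling is bookkeeping only (the recorded scale is the product of the
operand scales). The multiplicative depth budget is
`length(coeff_modulus_bits) - 1`. `backend = "emulated"` keeps the exact
same bookkeeping (levels, scales, packing, rotation counts, partial
decryptions, smudging-sized perturbations) over plaintext slot vectors at
full slot width, storing every exchanged payload whitened by a
nonce-keyed pseudo-random offset so that no file in the shared space
contains raw values. The emulation preserves the protocol observables at
plaintext speed; it does not provide cryptographic security, which is why
the contract test-suite runs identically against both backends.

## Encrypted matrix algebra

Matrices are flattened row-major into $\lceil ab/\text{slots}\rceil$
ciphertexts (8,192 slots at $n = 16384$; 57,344 packed values occupy 7
ciphertexts). The product $A_{a\times b} B_{b\times c}$ is assembled as
$\sum_{i\le b} ce_i(A) \odot re_i(B)$ from column expansions (column $i$
replicated) and row expansions (row $i$ replicated), which are distributive
over addition — that is what lets per-site plaintext expansions be pooled
by encrypted summation. Per-row inner products use one elementwise product
followed by $\log_2 b$ rotate-and-add rounds per ciphertext and a 0/1
selector plaintext that keeps every $b$-th slot; columns must be
zero-padded to a power of two dividing the slot count so rows never
straddle ciphertexts. Rather than spending $a$ further rotations per block
to compact the result, the output keeps a recorded slot stride and all
later consumers (elementwise arithmetic, masking, decryption) honor that
layout; per-variant vectors that must align with it (the $G'WG$ diagonal,
the positive score masks) are encoded directly in the strided layout. Row
expansions of *encrypted* matrices isolate a row with a selector (one
level), hoist it to the top of the block (one alignment rotation) and
replicate by $\log_2(\text{width})$ doubling rounds; the instrumented
replication-rotation count is exactly `rows * log2(width)`.

Scale alignment before additions is done by exact power-of-two scalar
multiplication (no level cost); level alignment by explicit level drops.
When the depth budget or, on the toy backend, the modulus headroom for the
grown scale runs out, a *collective refresh* restores a fresh encryption:
sites pool an additive mask, the masked matrix is collectively decrypted,
re-encrypted fresh by the lead site, and the mask is subtracted encrypted.

## Federated GWAS

**Null model (IRLS).** With current weights $\alpha$ each site computes
$\mu_0 = \text{logistic}(X\alpha)$ (clamped to $[10^{-8}, 1-10^{-8}]$),
$W = \mu_0(1-\mu_0)$, $z = X\alpha + (y-\mu_0)/W$, and the $p\times p$ and
$p\times 1$ aggregates $\Upsilon_s = X_s'W_sX_s$ and $X_s'W_sz_s$. The
pooled $\Upsilon = \sum_s \Upsilon_s$ is never revealed: each site uploads
encrypted expansions of a private Gaussian mask $H_s$, the pooled mask
$H = \sum_s H_s$ multiplies each site's plaintext $\Upsilon_s$ in the
encrypted domain, the pooled $\Upsilon H$ is collectively decrypted,
inverted in plaintext ($p \times p$, before padding, so no singular padded
block arises), and re-multiplied by the encrypted $H$ to leave
$pad(\Upsilon^{-1})$ encrypted at the next power-of-two size. The update
$\alpha_{new} = pad(\Upsilon^{-1}) \, pad(X'Wz)$ uses an encrypted row
expansion and one row-row product and is collectively decrypted each epoch
(the weight vector itself is treated as releasable, as the intermediate
estimates are in the underlying protocol). Defaults: $\alpha_0 = 0$,
tolerance $10^{-4}$ on $\max|\Delta\alpha|$, at most 10 epochs. A
perfectly separable cohort exhausts the epoch cap with a warning — the
usual IRLS pathology. Scoring reuses the final epoch's $W$, $\mu_0$ and
encrypted inverse.

**Score test.** Per variant, the score numerator $T = \sum_s G_s'(y_s -
\mu_{0,s})$ and variance $S = \mathrm{diag}(G'WG) -
\mathrm{rowdot}(G'WX,\; G'WX\,\Upsilon^{-1})$ are pooled encrypted; the
diagonal is computed directly per variant ($\sum_i w_i g_i^2$) since the
full $M \times M$ product is never needed. $T$ cannot be decrypted as-is
(it leaks genotype information), so $T$ is squared homomorphically after
pooling and one common positive per-variant mask — the sum of per-site
$\mathrm{Uniform}(0.5, 1.5)$ vectors, bounded away from zero — multiplies
both $T^2$ and $S$ before collective decryption. A common factor cancels
exactly in $T^2/S$, which is $\chi^2_1$ under the null. Squaring before
masking is deliberate: one scalar on $T$ and $S$ would *not* preserve
$T^2/S$, so the package applies the mask to the already-squared numerator.
The masking jitters the magnitudes of $T^2$ and $S$ (by the unknown factor
in $[S/2, 3S/2]$) but leaves their ratio exact; it does not make the
masked values statistically independent of the true ones, and the vignette
flags this as the protocol's accepted leakage. Variants whose decrypted
$S$ is non-positive are reported with missing p-values.

**Meta-analysis.** Each site fits its own plaintext null model and computes
local $T_s, S_s$; the encrypted vectors are pooled by summation, $\sum T$
is squared homomorphically, the same positive-mask construction is applied,
and $(\sum T)^2 / \sum S$ gets $\chi^2_1$ p-values. Masking after pooling
and masking before pooling commute for a summed mask; the implementation
masks the pooled quantities.

## The simulator and what it does (not) show

The generator emulates a 3-population federated design without any external
data: ancestral allele frequencies $\mathrm{Uniform}(0.05, 0.95)$,
per-population frequencies from the Balding–Nichols Beta with $F_{st} =
0.05$ by default, genotypes $\mathrm{Binomial}(2, p_{pop})$ independent
across variants. Phenotypes follow a liability threshold: $\eta = G\beta +
0.1\,\mathrm{gender} + \varepsilon$ with 20 causal variants,
$\beta \sim \mathrm{Uniform}(-0.5, 0.5)$, $\varepsilon \sim N(0, 0.5)$
(variance), and $Y = 1$ iff $\eta > 0$ (the measure-zero boundary
$\eta = 0$ maps to 0). Half of each cohort is female; covariates are an
intercept, gender and the top 8 principal components of the pooled
standardized genotypes. Degenerate all-case/all-control draws are redrawn
with the next seed, with a warning. The model has no linkage
disequilibrium, no realistic frequency spectrum, no kinship and no
missingness mechanism beyond what the caller injects, so passing tests
demonstrate protocol correctness and statistical calibration on exchangeable
variants — not robustness to the correlation structure of real genomes.

The reference oracles are deliberately independent of the federated code
path: the pooled null model uses `stats::glm`/`glm.fit`, the per-variant
Wald test refits covariates-plus-genotype logistic regressions, and the
rank concordance is the squared Spearman correlation with mid-ranked ties.

## Numerical choices

* Toy ring: test default $n = 64$–$1024$, scale $2^{30}$, modulus $\approx
  100$ bits; key-switching digits of 4 bits keep the per-rotation noise
  near $10^{-4}$ of the encoding resolution at $n = 1024$. Coefficient
  reductions of encode outputs go through exact 128-bit integer arithmetic
  because double modular reduction loses exactness beyond $2^{52}$.
* Threshold-decryption checks at default 40-bit smudging use scale
  $2^{35}$ so the decoded smudging error stays below $10^{-2}$ at small
  $n$; the end-to-end demo on the toy backend runs at scale $2^{30}$ with
  20-bit smudging and a depth-2 modulus, relying on collective refreshes
  between multiplication chains. Refresh masks are encoded at the
  ciphertext's grown scale, so their spread is capped by the remaining
  modulus headroom (the mask still dominates the bounded data range the
  modulus can represent at that scale).
* Comparison tolerances on encrypted-vs-plaintext oracles are $10^{-2}$
  absolute at the default scales and are scale-dependent.
* Multiplicative masks are square Gaussian matrices (almost surely
  invertible); a condition-number guard ($\kappa > 10^8$) reseeds.
* Mean imputation is site-local per variant; all-missing variants are
  flagged and excluded from inference.

## Study sizes used in the checks

The packaged acceptance analyses run a 3-site, 400-subjects-per-site,
2,048-variant cohort with the generator defaults above — the package's
chosen desk-scale rendition of the three-population design — and report
secure-vs-plaintext-federated, secure-vs-pooled-Wald and
meta-vs-pooled-Wald Spearman $R^2$. At this cohort size the first two
concordances sit at or above 0.99; the summary-statistic meta-analysis is
noticeably noisier at 400 subjects per site (per-site null models with 10
covariates, variants rare within single populations) and its concordance
with the pooled Wald oracle typically falls in 0.90–0.94, recovering above
0.97 from roughly 800 subjects per site — the expected cost of
meta-analysis relative to raw-data federation, amplified by the small
per-site samples.

## Known limitations

No bootstrapping or key switching between public keys; the toy backend's
parameters are demonstration-scale and make no hardness claims; the
emulated backend's privacy is structural (whitened payloads), not
cryptographic; the honest-but-curious model is assumed throughout — a site
deviating from the protocol can corrupt results or decrypt unintended
values, as the underlying protocol itself acknowledges.
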