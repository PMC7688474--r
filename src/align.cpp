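#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -1e30;
static const double EPS = 1e-9;

static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// EDNAFULL-like: any ambiguity code (incl. N) scores -2 against everything
// and never counts as identical.
static inline double pair_score(char a, char b, double match, double mismatch) {
    if (!is_acgt(a) || !is_acgt(b)) return -2.0;
    return (a == b) ? match : mismatch;
}

struct AlnResult {
    double score;
    int n_identical;
    int alignment_length;
    std::string aligned_a;
    std::string aligned_b;
};

// DP cell value: lexicographic objective (score, n_identical, -alen).
// Among equal-score alignments the one with more identical columns wins,
// then the shorter one; all three components are invariant under swapping
// the sequences, which makes the reported identity symmetric.
struct Cell {
    double s;
    int nid;
    int alen;
    bool valid;
};

static inline Cell invalid_cell() { return Cell{NEG_INF, 0, 0, false}; }

static inline bool better(const Cell& a, const Cell& b) {
    if (!a.valid) return false;
    if (!b.valid) return true;
    if (a.s > b.s + EPS) return true;
    if (a.s < b.s - EPS) return false;
    if (a.nid != b.nid) return a.nid > b.nid;
    return a.alen < b.alen;
}

static inline bool same_cell(const Cell& a, const Cell& b) {
    return a.valid && b.valid && std::fabs(a.s - b.s) <= EPS &&
        a.nid == b.nid && a.alen == b.alen;
}

static inline Cell advance(const Cell& c, double ds, int dnid, int dalen) {
    if (!c.valid) return invalid_cell();
    return Cell{c.s + ds, c.nid + dnid, c.alen + dalen, true};
}

// Gotoh 3-state global alignment. Gap of length L costs
// gap_open + (L-1)*gap_extend. With end_gaps_free, leading/trailing gaps
// cost nothing but still count in the alignment length / identity
// denominator (EMBOSS needle, endweight=false). The deterministic
// objective refinement (see Cell) is shared with the R test oracle.
static AlnResult nw_core(const std::string& a, const std::string& b,
                         double match, double mismatch,
                         double gap_open, double gap_extend,
                         bool end_gaps_free) {
    const int m = (int) a.size(), n = (int) b.size();
    const size_t w = (size_t) n + 1;
    std::vector<Cell> M((size_t)(m + 1) * w, invalid_cell());
    std::vector<Cell> X((size_t)(m + 1) * w, invalid_cell());  // consumes a
    std::vector<Cell> Y((size_t)(m + 1) * w, invalid_cell());  // consumes b

    M[0] = Cell{0.0, 0, 0, true};
    for (int i = 1; i <= m; ++i)
        X[(size_t)i * w] = Cell{end_gaps_free ? 0.0 :
                                -(gap_open + (i - 1) * gap_extend), 0, i, true};
    for (int j = 1; j <= n; ++j)
        Y[(size_t)j] = Cell{end_gaps_free ? 0.0 :
                            -(gap_open + (j - 1) * gap_extend), 0, j, true};

    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const size_t c = (size_t)i * w + j, d = (size_t)(i - 1) * w + (j - 1);
            const size_t u = (size_t)(i - 1) * w + j, l = c - 1;
            double s = pair_score(a[i - 1], b[j - 1], match, mismatch);
            int id = (a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ? 1 : 0;
            Cell best = M[d];
            if (better(X[d], best)) best = X[d];
            if (better(Y[d], best)) best = Y[d];
            M[c] = advance(best, s, id, 1);
            Cell x = advance(M[u], -gap_open, 0, 1);
            Cell x2 = advance(X[u], -gap_extend, 0, 1);
            if (better(x2, x)) x = x2;
            x2 = advance(Y[u], -gap_open, 0, 1);
            if (better(x2, x)) x = x2;
            X[c] = x;
            Cell y = advance(M[l], -gap_open, 0, 1);
            Cell y2 = advance(Y[l], -gap_extend, 0, 1);
            if (better(y2, y)) y = y2;
            y2 = advance(X[l], -gap_open, 0, 1);
            if (better(y2, y)) y = y2;
            Y[c] = y;
        }
    }

    // end cell: add the free-tail contribution to the objective so ties
    // resolve on the full alignment, then prefer larger i, then larger j
    auto cellbest = [&](int i, int j) {
        const size_t c = (size_t)i * w + j;
        Cell v = M[c];
        if (better(X[c], v)) v = X[c];
        if (better(Y[c], v)) v = Y[c];
        return v;
    };
    int bi = m, bj = n;
    Cell btot = invalid_cell();
    if (end_gaps_free) {
        for (int i = 0; i < m; ++i) {
            Cell v = advance(cellbest(i, n), 0, 0, m - i);
            if (better(v, btot) || same_cell(v, btot)) { btot = v; bi = i; bj = n; }
        }
        for (int j = 0; j <= n; ++j) {
            Cell v = advance(cellbest(m, j), 0, 0, n - j);
            if (better(v, btot) || same_cell(v, btot)) { btot = v; bi = m; bj = j; }
        }
    } else {
        btot = cellbest(m, n);
    }

    // state at the end cell
    const size_t bc = (size_t)bi * w + bj;
    const int tail = end_gaps_free ? (m - bi) + (n - bj) : 0;
    Cell bcell = advance(btot, 0, 0, -tail);  // objective at the cell itself
    int state;  // 0 = M, 1 = X, 2 = Y
    if (same_cell(M[bc], bcell)) state = 0;
    else if (same_cell(X[bc], bcell)) state = 1;
    else state = 2;

    // traceback
    std::string ra, rb;  // built reversed
    for (int j = n; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
    for (int i = m; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

    int i = bi, j = bj;
    Cell cur = bcell;
    while (i > 0 || j > 0) {
        if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue; }
        if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
        const size_t d = (size_t)(i - 1) * w + (j - 1);
        const size_t u = (size_t)(i - 1) * w + j, l = (size_t)i * w + (j - 1);
        if (state == 0) {
            double s = pair_score(a[i - 1], b[j - 1], match, mismatch);
            int id = (a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ? 1 : 0;
            Cell target = advance(cur, -s, -id, -1);
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            if (same_cell(M[d], target)) state = 0;
            else if (same_cell(X[d], target)) state = 1;
            else state = 2;
            cur = target;
            --i; --j;
        } else if (state == 1) {
            ra.push_back(a[i - 1]); rb.push_back('-');
            Cell t_open = advance(cur, gap_open, 0, -1);
            Cell t_ext = advance(cur, gap_extend, 0, -1);
            if (same_cell(M[u], t_open)) { state = 0; cur = t_open; }
            else if (same_cell(X[u], t_ext)) { state = 1; cur = t_ext; }
            else { state = 2; cur = t_open; }
            --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]);
            Cell t_open = advance(cur, gap_open, 0, -1);
            Cell t_ext = advance(cur, gap_extend, 0, -1);
            if (same_cell(M[l], t_open)) { state = 0; cur = t_open; }
            else if (same_cell(Y[l], t_ext)) { state = 2; cur = t_ext; }
            else { state = 1; cur = t_open; }
            --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    AlnResult res;
    res.score = btot.s;
    res.alignment_length = (int) ra.size();
    int nid = 0;
    for (size_t k = 0; k < ra.size(); ++k)
        if (ra[k] == rb[k] && is_acgt(ra[k])) ++nid;
    res.n_identical = nid;
    res.aligned_a = ra;
    res.aligned_b = rb;
    return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool end_gaps_free) {
    AlnResult r = nw_core(a, b, match, mismatch, gap_open, gap_extend, end_gaps_free);
    double id = r.alignment_length > 0 ?
        100.0 * r.n_identical / r.alignment_length : 0.0;
    return List::create(
        _["score"] = r.score,
        _["identity_pct"] = id,
        _["alignment_length"] = r.alignment_length,
        _["n_identical"] = r.n_identical,
        _["aligned_a"] = r.aligned_a,
        _["aligned_b"] = r.aligned_b);
}

// ---- degenerate primer search -------------------------------------------

static inline int iupac_mask(char c) {
    switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
    }
}

// Semi-global edit distance of the whole primer against any substring of
// seq (unit costs; a primer base matches a target base iff their IUPAC
// expansions intersect). Returns c(start, end, dist), 1-based inclusive,
// of the best locus (min dist; ties -> leftmost start, then shortest
// span), or integer(0) if the best distance exceeds `budget`.
// [[Rcpp::export]]
IntegerVector primer_search_cpp(std::string seq, std::string primer, int budget) {
    const int n = (int) seq.size(), m = (int) primer.size();
    if (m == 0) stop("empty primer");
    std::vector<int> pmask(m);
    for (int i = 0; i < m; ++i) {
        pmask[i] = iupac_mask(primer[i]);
        if (pmask[i] == 0) stop("invalid IUPAC code in primer: '%s'",
                                std::string(1, primer[i]).c_str());
    }
    std::vector<int> dp(n + 1), dc(n + 1);   // distance, previous/current row
    std::vector<int> sp(n + 1), sc(n + 1);   // best (smallest) start per cell
    for (int j = 0; j <= n; ++j) { dp[j] = 0; sp[j] = j + 1; }
    for (int i = 1; i <= m; ++i) {
        dc[0] = i; sc[0] = 1;
        for (int j = 1; j <= n; ++j) {
            int tmask = iupac_mask(seq[j - 1]);
            int cost = (pmask[i - 1] & tmask) ? 0 : 1;
            int d = dp[j - 1] + cost, s = sp[j - 1];             // diagonal
            int d2 = dp[j] + 1, s2 = sp[j];                      // gap in seq
            if (d2 < d || (d2 == d && s2 < s)) { d = d2; s = s2; }
            int d3 = dc[j - 1] + 1, s3 = sc[j - 1];              // gap in primer
            if (d3 < d || (d3 == d && s3 < s)) { d = d3; s = s3; }
            dc[j] = d; sc[j] = s;
        }
        std::swap(dp, dc); std::swap(sp, sc);
    }
    int bestd = budget + 1, bests = -1, beste = -1;
    for (int j = 1; j <= n; ++j) {
        if (dp[j] < bestd ||
            (dp[j] == bestd && (sp[j] < bests))) {
            bestd = dp[j]; bests = sp[j]; beste = j;
        }
    }
    if (bestd > budget || bests < 0 || beste < bests)
        return IntegerVector(0);
    return IntegerVector::create(bests, beste, bestd);
}

// ---- greedy identity clustering -----------------------------------------

// identity fraction with denominator = shorter sequence length.
// Equal lengths: ungapped comparison with early exit once the identity
// cannot reach `threshold` any more (returns -1 on early exit).
static double identity_frac(const std::string& a, const std::string& b,
                            double threshold,
                            double match, double mismatch,
                            double gap_open, double gap_extend) {
    const int la = (int) a.size(), lb = (int) b.size();
    if (la == lb) {
        int allowed = (int) std::floor(la * (1.0 - threshold) + EPS);
        int mm = 0;
        for (int k = 0; k < la; ++k) {
            if (a[k] != b[k] || !is_acgt(a[k])) {
                if (++mm > allowed) return -1.0;
            }
        }
        return (double)(la - mm) / la;
    }
    AlnResult r = nw_core(a, b, match, mismatch, gap_open, gap_extend, true);
    return (double) r.n_identical / std::min(la, lb);
}

// Sequences must already be sorted (length-descending, ties input order).
// Returns the 1-based cluster id of every sequence, clusters numbered in
// founding order; each sequence joins the *most similar* representative
// with identity >= threshold (ties -> earliest-founded), else founds a
// new cluster.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
    const int n = seqs.size();
    IntegerVector assign(n);
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
    std::vector<int> reps;
    for (int i = 0; i < n; ++i) {
        double best = -1.0; int bestc = -1;
        for (size_t r = 0; r < reps.size(); ++r) {
            double id = identity_frac(ss[i], ss[reps[r]], threshold,
                                      match, mismatch, gap_open, gap_extend);
            if (id >= threshold - 1e-12 && id > best + 1e-12) {
                best = id; bestc = (int) r;
            }
        }
        if (bestc < 0) {
            reps.push_back(i);
            assign[i] = (int) reps.size();
        } else {
            assign[i] = bestc + 1;
        }
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return assign;
}

// Batch alignment statistics of one query against many references:
// rows n_identical, alignment_length. Equal-length pairs use the ungapped
// statistics (optimal under this scoring at the high-identity regime the
// gates care about); unequal lengths run the full aligner.
// [[Rcpp::export]]
IntegerMatrix batch_align_stats_cpp(std::string query, CharacterVector refs,
                                    double match, double mismatch,
                                    double gap_open, double gap_extend) {
    const int n = refs.size();
    IntegerMatrix out(2, n);
    const int lq = (int) query.size();
    for (int i = 0; i < n; ++i) {
        std::string r = as<std::string>(refs[i]);
        if ((int) r.size() == lq) {
            int nid = 0;
            for (int k = 0; k < lq; ++k)
                if (query[k] == r[k] && is_acgt(query[k])) ++nid;
            out(0, i) = nid;
            out(1, i) = lq;
        } else {
            AlnResult a = nw_core(query, r, match, mismatch,
                                  gap_open, gap_extend, true);
            out(0, i) = a.n_identical;
            out(1, i) = a.alignment_length;
        }
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// ---- paired-end read merging --------------------------------------------

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
    }
}

// FLASH-style overlap merge. Candidate overlaps in [min_overlap,
// max_overlap] are scored by mismatch ratio; best = lowest ratio, ties ->
// longest overlap; accepted if ratio <= max_mismatch_ratio. At overlap
// mismatches the base with the higher Phred score wins (ties -> forward).
// [[Rcpp::export]]
List merge_pair_cpp(std::string fseq, std::string fqual,
                    std::string rseq, std::string rqual,
                    int min_overlap, int max_overlap,
                    double max_mismatch_ratio) {
    const int lf = (int) fseq.size(), lr = (int) rseq.size();
    if (lf == 0 || lr == 0) return List::create(_["merged"] = false);
    std::string rc(lr, 'N'), rq(lr, '!');
    for (int k = 0; k < lr; ++k) {
        rc[k] = comp_base(rseq[lr - 1 - k]);
        rq[k] = rqual[lr - 1 - k];
    }
    const int omax = std::min(max_overlap, std::min(lf, lr));
    double best_ratio = 2.0; int best_o = -1;
    for (int o = min_overlap; o <= omax; ++o) {
        int mm = 0;
        const int off = lf - o;
        for (int k = 0; k < o; ++k)
            if (fseq[off + k] != rc[k]) ++mm;
        double ratio = (double) mm / o;
        if (ratio < best_ratio - EPS ||
            (ratio < best_ratio + EPS && o > best_o)) {
            best_ratio = ratio; best_o = o;
        }
    }
    if (best_o < 0 || best_ratio > max_mismatch_ratio + EPS)
        return List::create(_["merged"] = false);
    const int off = lf - best_o;
    std::string seq = fseq.substr(0, off), qual = fqual.substr(0, off);
    for (int k = 0; k < best_o; ++k) {
        char fb = fseq[off + k], rb = rc[k];
        char fq = fqual[off + k], q2 = rq[k];
        if (fb == rb) {
            seq.push_back(fb);
            qual.push_back(fq >= q2 ? fq : q2);
        } else if (q2 > fq) {
            seq.push_back(rb); qual.push_back(q2);
        } else {
            seq.push_back(fb); qual.push_back(fq);
        }
    }
    seq += rc.substr(best_o);
    qual += rq.substr(best_o);
    return List::create(
        _["merged"] = true,
        _["sequence"] = seq,
        _["quality"] = qual,
        _["overlap"] = best_o,
        _["mismatch_ratio"] = best_ratio);
}
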