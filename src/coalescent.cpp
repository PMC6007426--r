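// Structured-coalescent engine.
//
// Time runs backwards in units of 2*Nref generations.  A demographic model
// is a sequence of epochs; each epoch carries per-deme relative sizes (nu),
// a backwards migration-rate matrix (rate per lineage per unit time that a
// lineage in deme i jumps to deme j; equals 2*Nref*m_forward for forward
// fraction m), and a deme remap applied when crossing into the epoch.
// Pairwise coalescence rate within a deme of size nu is 1/nu per unit time.
//
// A lineage's descendant-count vector is constant over its lifetime, so
// branch-length accounting is done once per lineage at its death
// (coalescence) rather than per waiting interval.
//
// All randomness goes through R's RNG so set.seed() in R governs everything.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct EpochModel {
    int ndeme;
    int nepoch;
    std::vector<double> start;              // epoch start times, ascending, start[0]=0
    const double *nu;                       // ndeme x nepoch
    const double *mig;                      // ndeme x ndeme x nepoch
    const int *remap;                       // ndeme x nepoch, 1-based from R
    double nu_at(int d, int e) const { return nu[d + (size_t)ndeme * e]; }
    double mig_at(int i, int j, int e) const {
        return mig[i + (size_t)ndeme * (j + (size_t)ndeme * e)];
    }
    int remap_at(int d, int e) const { return remap[d + (size_t)ndeme * e] - 1; }
};

EpochModel make_model(const NumericVector &epoch_start, const NumericMatrix &nu,
                      const NumericVector &mig, const IntegerMatrix &remap) {
    EpochModel m;
    m.ndeme = nu.nrow();
    m.nepoch = nu.ncol();
    m.start.assign(epoch_start.begin(), epoch_start.end());
    if ((int)m.start.size() != m.nepoch)
        stop("epoch_start length must equal number of epochs");
    if ((int)mig.size() != m.ndeme * m.ndeme * m.nepoch)
        stop("migration array has wrong size");
    if (remap.nrow() != m.ndeme || remap.ncol() != m.nepoch)
        stop("remap has wrong shape");
    m.nu = nu.begin();
    m.mig = mig.begin();
    m.remap = remap.begin();
    return m;
}

struct Sim {
    const EpochModel *M;
    int npop;
    std::vector<int> deme;      // active lineage demes
    std::vector<int> cnt;       // active lineage x npop descendant counts
    std::vector<double> lbirth; // active lineage birth times
    std::vector<int> id;        // branch id of each active lineage (mutation mode)
    int k;                      // active lineage count

    bool track_branches;
    std::vector<std::vector<int>> leafset;  // by branch id
    std::vector<double> blen;               // by branch id (set at death)

    double t, tmrca, total_len;

    void init(const EpochModel &mod, const IntegerVector &sample_sizes,
              const IntegerVector &sample_demes, bool branches) {
        M = &mod;
        npop = sample_sizes.size();
        track_branches = branches;
        k = 0;
        deme.clear(); cnt.clear(); lbirth.clear(); id.clear();
        leafset.clear(); blen.clear();
        int leaf = 0;
        for (int p = 0; p < npop; ++p) {
            for (int i = 0; i < sample_sizes[p]; ++i) {
                deme.push_back(sample_demes[p] - 1);
                for (int q = 0; q < npop; ++q) cnt.push_back(q == p ? 1 : 0);
                lbirth.push_back(0.0);
                if (track_branches) {
                    id.push_back((int)leafset.size());
                    leafset.push_back(std::vector<int>(1, leaf));
                    blen.push_back(0.0);
                }
                ++leaf; ++k;
            }
        }
        t = 0.0; tmrca = 0.0; total_len = 0.0;
    }

    void remove_lineage(int i) {
        deme[i] = deme[k - 1];
        for (int q = 0; q < npop; ++q) cnt[i * npop + q] = cnt[(k - 1) * npop + q];
        lbirth[i] = lbirth[k - 1];
        if (track_branches) id[i] = id[k - 1];
        --k;
    }

    // run to the MRCA; coal_cb(ia, ib) is invoked at each coalescence
    // BEFORE the pair is merged (ia, ib index the two dying lineages).
    template <class CoalCb>
    void run(CoalCb coal_cb) {
        int e = 0;
        const EpochModel &m = *M;
        std::vector<double> coal_rate(m.ndeme), mig_rate(m.ndeme), mig_row(m.ndeme);
        std::vector<int> kd(m.ndeme);
        while (k > 1) {
            // advance epoch pointer, applying remaps at boundaries
            while (e + 1 < m.nepoch && t >= m.start[e + 1] - 1e-15) {
                ++e;
                for (int i = 0; i < k; ++i) deme[i] = m.remap_at(deme[i], e);
            }
            std::fill(kd.begin(), kd.end(), 0);
            for (int i = 0; i < k; ++i) ++kd[deme[i]];
            double R = 0.0;
            for (int d = 0; d < m.ndeme; ++d) {
                coal_rate[d] = kd[d] > 1 ? 0.5 * kd[d] * (kd[d] - 1) / m.nu_at(d, e) : 0.0;
                double row = 0.0;
                for (int j = 0; j < m.ndeme; ++j)
                    if (j != d) row += m.mig_at(d, j, e);
                mig_row[d] = row;
                mig_rate[d] = kd[d] * row;
                R += coal_rate[d] + mig_rate[d];
            }
            double t_next = (e + 1 < m.nepoch) ? m.start[e + 1] : R_PosInf;
            double dt = (R > 0.0) ? R::exp_rand() / R : R_PosInf;
            if (t + dt >= t_next) {        // cross the epoch boundary, no event
                if (!R_finite(t_next))
                    stop("genealogy failed to coalesce: disconnected demes in final epoch");
                t = t_next;
                continue;
            }
            t += dt;
            double u = unif_rand() * R;
            int d = 0;
            bool coal = false;
            for (d = 0; d < m.ndeme; ++d) {
                if (u < coal_rate[d]) { coal = true; break; }
                u -= coal_rate[d];
                if (u < mig_rate[d]) { coal = false; break; }
                u -= mig_rate[d];
            }
            if (d >= m.ndeme) d = m.ndeme - 1;   // numerical guard
            if (coal) {
                // choose an unordered pair among the kd[d] lineages in deme d
                int a = (int)(unif_rand() * kd[d]);
                int b = (int)(unif_rand() * (kd[d] - 1));
                if (b >= a) ++b;
                if (a >= kd[d]) a = kd[d] - 1;
                if (b >= kd[d]) b = a == kd[d] - 1 ? kd[d] - 2 : kd[d] - 1;
                int ia = -1, ib = -1, seen = 0;
                for (int i = 0; i < k; ++i) {
                    if (deme[i] == d) {
                        if (seen == a) ia = i;
                        if (seen == b) ib = i;
                        ++seen;
                    }
                }
                coal_cb(ia, ib);
                total_len += (t - lbirth[ia]) + (t - lbirth[ib]);
                if (track_branches) {
                    blen[id[ia]] = t - lbirth[ia];
                    blen[id[ib]] = t - lbirth[ib];
                    std::vector<int> merged(leafset[id[ia]]);
                    merged.insert(merged.end(), leafset[id[ib]].begin(),
                                  leafset[id[ib]].end());
                    id[ia] = (int)leafset.size();
                    leafset.push_back(merged);
                    blen.push_back(0.0);
                }
                for (int q = 0; q < npop; ++q)
                    cnt[ia * npop + q] += cnt[ib * npop + q];
                lbirth[ia] = t;
                remove_lineage(ib);
            } else {
                // migration out of deme d
                double v = unif_rand() * mig_row[d];
                int j = 0;
                for (j = 0; j < m.ndeme; ++j) {
                    if (j == d) continue;
                    double r = m.mig_at(d, j, e);
                    if (v < r) break;
                    v -= r;
                }
                if (j >= m.ndeme || j == d) j = (d + 1) % m.ndeme;
                int pick = (int)(unif_rand() * kd[d]);
                int seen = 0;
                for (int i = 0; i < k; ++i) {
                    if (deme[i] == d) {
                        if (seen == pick) { deme[i] = j; break; }
                        ++seen;
                    }
                }
            }
        }
        tmrca = t;
    }
};

} // namespace

// Accumulated branch length per joint descendant-count cell, summed over
// independent genealogies.  Returns a flat array of dim prod(sample_sizes+1);
// cell (j1,..,jP) indexes lineages ancestral to j_p sampled haplotypes of
// population p.  Dividing by the sum gives the expected unfolded joint SFS
// under infinite sites.
// [[Rcpp::export]]
NumericVector cpp_branch_sfs(NumericVector epoch_start, NumericMatrix nu,
                             NumericVector mig, IntegerMatrix remap,
                             IntegerVector sample_sizes, IntegerVector sample_demes,
                             int reps) {
    EpochModel m = make_model(epoch_start, nu, mig, remap);
    int npop = sample_sizes.size();
    std::vector<int> stride(npop);
    size_t ncell = 1;
    for (int p = 0; p < npop; ++p) {
        stride[p] = (int)ncell;
        ncell *= sample_sizes[p] + 1;
    }
    NumericVector out((R_xlen_t)ncell);
    double *acc = out.begin();
    Sim s;
    for (int r = 0; r < reps; ++r) {
        s.init(m, sample_sizes, sample_demes, false);
        const int *cnt = s.cnt.data();
        const double *birth = s.lbirth.data();
        s.run([&](int ia, int ib) {
            for (int which = 0; which < 2; ++which) {
                int i = which ? ib : ia;
                size_t idx = 0;
                for (int p = 0; p < npop; ++p)
                    idx += (size_t)stride[p] * cnt[i * npop + p];
                acc[idx] += s.t - birth[i];
            }
        });
        if ((r & 4095) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Per-replicate genealogy summaries: TMRCA and total branch length
// (scaled time units).
// [[Rcpp::export]]
NumericMatrix cpp_genealogy_stats(NumericVector epoch_start, NumericMatrix nu,
                                  NumericVector mig, IntegerMatrix remap,
                                  IntegerVector sample_sizes, IntegerVector sample_demes,
                                  int reps) {
    EpochModel m = make_model(epoch_start, nu, mig, remap);
    NumericMatrix out(reps, 2);
    Sim s;
    for (int r = 0; r < reps; ++r) {
        s.init(m, sample_sizes, sample_demes, false);
        s.run([](int, int) {});
        out(r, 0) = s.tmrca;
        out(r, 1) = s.total_len;
        if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Simulate one non-recombining locus: genealogy plus infinite-sites
// mutations at rate theta_locus/2 per unit branch length (theta_locus =
// 4*Nref*mu*L).  Returns a 0/1 matrix with one row per segregating site and
// one column per sampled haplotype (populations in input order).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_locus(NumericVector epoch_start, NumericMatrix nu,
                            NumericVector mig, IntegerMatrix remap,
                            IntegerVector sample_sizes, IntegerVector sample_demes,
                            double theta_locus) {
    EpochModel m = make_model(epoch_start, nu, mig, remap);
    int nhap = 0;
    for (int p = 0; p < sample_sizes.size(); ++p) nhap += sample_sizes[p];
    Sim s;
    s.init(m, sample_sizes, sample_demes, true);
    s.run([](int, int) {});
    // root branch gets zero length (it carries no observable mutation)
    int nbranch = (int)s.leafset.size();
    std::vector<double> cum(nbranch, 0.0);
    double tot = 0.0;
    for (int b = 0; b < nbranch; ++b) {
        double l = s.blen[b];
        if ((int)s.leafset[b].size() == nhap) l = 0.0;  // spans all samples
        tot += l;
        cum[b] = tot;
    }
    int S = (tot > 0 && theta_locus > 0)
                ? (int)R::rpois(0.5 * theta_locus * tot) : 0;
    IntegerMatrix geno(S, nhap);
    for (int si = 0; si < S; ++si) {
        double u = unif_rand() * tot;
        int lo = 0, hi = nbranch - 1;
        while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cum[mid] <= u) lo = mid + 1; else hi = mid;
        }
        for (int leaf : s.leafset[lo]) geno(si, leaf) = 1;
    }
    return geno;
}
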