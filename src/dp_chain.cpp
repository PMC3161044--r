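// Compiled core of the Dirichlet-process genotype clustering sampler.
//
// Genotypes arrive as an n x (ploidy*L) integer matrix of 0-based dense
// allele codes, -1 for missing. All randomness goes through R's RNG so a
// single set.seed() call makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Dirichlet-multinomial machinery
// ---------------------------------------------------------------------------

// Holds the genotype matrix plus per-locus log-gamma caches so that the
// predictive probability of one individual is a handful of table lookups.
// Caches are rebuilt for a locus whenever its lambda changes.
struct DMData {
    int n, L, P, totJ;
    const int *g;                 // column-major n x (P*L)
    std::vector<int> J, off;      // per-locus allele counts, offsets into totJ
    std::vector<double> lambda;   // per-locus Dirichlet hyperparameter
    int cachemax;
    std::vector<std::vector<double> > lgA;  // lgA[l][k] = lgamma(k + lambda_l)
    std::vector<std::vector<double> > lgB;  // lgB[l][k] = lgamma(k + J_l*lambda_l)

    DMData(const IntegerMatrix &gm, const IntegerVector &Jv, int ploidy,
           const NumericVector &lam)
        : n(gm.nrow()), L(Jv.size()), P(ploidy), g(&gm[0]) {
        J.assign(Jv.begin(), Jv.end());
        off.resize(L + 1);
        off[0] = 0;
        for (int l = 0; l < L; ++l) off[l + 1] = off[l] + std::max(J[l], 0);
        totJ = off[L];
        lambda.assign(lam.begin(), lam.end());
        cachemax = P * n + P + 2;
        lgA.resize(L);
        lgB.resize(L);
        for (int l = 0; l < L; ++l) build_cache(l);
    }

    void build_cache(int l) {
        lgA[l].resize(cachemax);
        lgB[l].resize(cachemax);
        double lam = lambda[l], Jlam = J[l] * lambda[l];
        for (int k = 0; k < cachemax; ++k) {
            lgA[l][k] = R::lgammafn(k + lam);
            lgB[l][k] = R::lgammafn(k + Jlam);
        }
    }

    inline int geno(int i, int slot) const { return g[(size_t)slot * n + i]; }

    // log predictive probability of individual i's multilocus genotype given
    // the allele-copy counts of one cluster (y/yl may be NULL = empty cluster)
    double logpred(int i, const int *y, const int *yl) const {
        double lp = 0.0;
        for (int l = 0; l < L; ++l) {
            if (J[l] < 1) continue;
            int c1 = geno(i, P * l);
            int c2 = (P == 2) ? geno(i, P * l + 1) : -1;
            int m = (c1 >= 0) + (c2 >= 0);
            if (m == 0) continue;
            int tot = yl ? yl[l] : 0;
            lp += lgB[l][tot] - lgB[l][tot + m];
            if (m == 2) {
                int y1 = y ? y[off[l] + c1] : 0;
                if (c1 == c2) {
                    lp += lgA[l][y1 + 2] - lgA[l][y1];
                } else {
                    int y2 = y ? y[off[l] + c2] : 0;
                    lp += M_LN2 + lgA[l][y1 + 1] - lgA[l][y1]
                               + lgA[l][y2 + 1] - lgA[l][y2];
                }
            } else {
                int c = (c1 >= 0) ? c1 : c2;
                int y1 = y ? y[off[l] + c] : 0;
                lp += lgA[l][y1 + 1] - lgA[l][y1];
            }
        }
        return lp;
    }
};

// Cluster sufficient statistics: per-cluster allele-copy counts.
struct Clusters {
    const DMData *d;
    std::vector<std::vector<int> > y;   // [j][totJ]
    std::vector<std::vector<int> > yl;  // [j][L]
    std::vector<int> size;

    explicit Clusters(const DMData *dd) : d(dd) {}

    int K() const { return (int)size.size(); }

    int new_cluster() {
        y.push_back(std::vector<int>(d->totJ, 0));
        yl.push_back(std::vector<int>(d->L, 0));
        size.push_back(0);
        return K() - 1;
    }

    void add(int i, int j, int delta) {
        for (int l = 0; l < d->L; ++l) {
            if (d->J[l] < 1) continue;
            for (int s = 0; s < d->P; ++s) {
                int c = d->geno(i, d->P * l + s);
                if (c >= 0) {
                    y[j][d->off[l] + c] += delta;
                    yl[j][l] += delta;
                }
            }
        }
        size[j] += delta;
    }

    // remove cluster j, filling the hole with the last cluster; returns the
    // old index of the cluster that moved into j (== old K-1), or -1
    int drop(int j) {
        int last = K() - 1;
        if (j != last) {
            y[j].swap(y[last]);
            yl[j].swap(yl[last]);
            size[j] = size[last];
        }
        y.pop_back();
        yl.pop_back();
        size.pop_back();
        return (j != last) ? last : -1;
    }
};

static inline int sample_log_weights(const std::vector<double> &lw) {
    double mx = lw[0];
    for (size_t k = 1; k < lw.size(); ++k) if (lw[k] > mx) mx = lw[k];
    double tot = 0.0;
    std::vector<double> w(lw.size());
    for (size_t k = 0; k < lw.size(); ++k) { w[k] = std::exp(lw[k] - mx); tot += w[k]; }
    double u = unif_rand() * tot, acc = 0.0;
    for (size_t k = 0; k < lw.size(); ++k) {
        acc += w[k];
        if (u <= acc) return (int)k;
    }
    return (int)lw.size() - 1;
}

static void shuffle_in_place(std::vector<int> &v) {
    for (int k = (int)v.size() - 1; k > 0; --k) {
        int r = (int)std::floor(unif_rand() * (k + 1));
        if (r > k) r = k;
        std::swap(v[k], v[r]);
    }
}

// log marginal likelihood of a set of individuals forming one cluster,
// computed as a chain of predictives (order-invariant); scratch counts are
// supplied by the caller and reset here
static double log_marginal_members(const DMData &d, const std::vector<int> &mem,
                                   std::vector<int> &ys, std::vector<int> &yls) {
    std::fill(ys.begin(), ys.end(), 0);
    std::fill(yls.begin(), yls.end(), 0);
    double lp = 0.0;
    for (size_t k = 0; k < mem.size(); ++k) {
        int i = mem[k];
        lp += d.logpred(i, ys.data(), yls.data());
        for (int l = 0; l < d.L; ++l) {
            if (d.J[l] < 1) continue;
            for (int s = 0; s < d.P; ++s) {
                int c = d.geno(i, d.P * l + s);
                if (c >= 0) { ys[d.off[l] + c]++; yls[l]++; }
            }
        }
    }
    return lp;
}

// Dirichlet-multinomial log marginal at a single locus for one cluster's
// counts under hyperparameter lam (multinomial coefficients omitted: they
// cancel in every ratio this is used for)
static double dm_locus_loglik(const int *y, int yl, int J, double lam) {
    if (yl == 0) return 0.0;
    double lp = R::lgammafn(J * lam) - R::lgammafn(yl + J * lam);
    for (int h = 0; h < J; ++h)
        if (y[h] > 0) lp += R::lgammafn(y[h] + lam) - R::lgammafn(lam);
    return lp;
}

// ---------------------------------------------------------------------------
// The DP chain: Gibbs scans + SAMS merge-split + lambda MH
// ---------------------------------------------------------------------------

struct DPChain {
    DMData d;
    Clusters cl;
    std::vector<int> lab;
    double alpha;
    int lambda_mode;   // 0 fixed, 1 single shared, 2 unique per locus
    double delta, lambda_upper;
    // scratch buffers reused by SAMS
    std::vector<int> ysa, ylsa, ysb, ylsb, ysc, ylsc;
    long sams_split_prop = 0, sams_split_acc = 0;
    long sams_merge_prop = 0, sams_merge_acc = 0;
    long lambda_prop = 0, lambda_acc = 0;

    DPChain(const IntegerMatrix &g, const IntegerVector &J, int ploidy,
            const NumericVector &lam, double alpha_, int lmode,
            double delta_, double lupper, const IntegerVector &init)
        : d(g, J, ploidy, lam), cl(&d), alpha(alpha_), lambda_mode(lmode),
          delta(delta_), lambda_upper(lupper) {
        lab.assign(init.begin(), init.end());
        int K0 = 0;
        for (int i = 0; i < d.n; ++i) K0 = std::max(K0, lab[i] + 1);
        for (int j = 0; j < K0; ++j) cl.new_cluster();
        for (int i = 0; i < d.n; ++i) cl.add(i, lab[i], +1);
        for (int j = 0; j < cl.K(); ++j)
            if (cl.size[j] == 0) stop("initial labels contain an empty cluster");
        ysa.resize(d.totJ); ylsa.resize(d.L);
        ysb.resize(d.totJ); ylsb.resize(d.L);
        ysc.resize(d.totJ); ylsc.resize(d.L);
    }

    void remove_individual(int i) {
        int j = lab[i];
        cl.add(i, j, -1);
        if (cl.size[j] == 0) {
            int moved = cl.drop(j);
            if (moved >= 0)
                for (int k = 0; k < d.n; ++k)
                    if (lab[k] == moved) lab[k] = j;
        }
        lab[i] = -1;
    }

    void gibbs_scan() {
        std::vector<double> lw;
        for (int i = 0; i < d.n; ++i) {
            remove_individual(i);
            int K = cl.K();
            lw.resize(K + 1);
            for (int j = 0; j < K; ++j)
                lw[j] = std::log((double)cl.size[j])
                      + d.logpred(i, cl.y[j].data(), cl.yl[j].data());
            lw[K] = std::log(alpha) + d.logpred(i, NULL, NULL);
            int pick = sample_log_weights(lw);
            if (pick == K) pick = cl.new_cluster();
            lab[i] = pick;
            cl.add(i, pick, +1);
        }
    }

    void members_of(int j, std::vector<int> &out, int skip1, int skip2) const {
        out.clear();
        for (int i = 0; i < d.n; ++i)
            if (lab[i] == j && i != skip1 && i != skip2) out.push_back(i);
    }

    void sams_move() {
        if (d.n < 2) return;
        int i = (int)std::floor(unif_rand() * d.n);
        if (i >= d.n) i = d.n - 1;
        int j;
        do {
            j = (int)std::floor(unif_rand() * d.n);
            if (j >= d.n) j = d.n - 1;
        } while (j == i);

        if (lab[i] == lab[j]) {  // propose a split
            sams_split_prop++;
            int c = lab[i];
            std::vector<int> rest;
            members_of(c, rest, i, j);
            shuffle_in_place(rest);

            // grow S_i and S_j by sequential allocation
            std::fill(ysa.begin(), ysa.end(), 0); std::fill(ylsa.begin(), ylsa.end(), 0);
            std::fill(ysb.begin(), ysb.end(), 0); std::fill(ylsb.begin(), ylsb.end(), 0);
            std::vector<int> memi(1, i), memj(1, j);
            double logLi = d.logpred(i, NULL, NULL);
            double logLj = d.logpred(j, NULL, NULL);
            add_to_scratch(i, ysa, ylsa);
            add_to_scratch(j, ysb, ylsb);
            double logq = 0.0;
            for (size_t k = 0; k < rest.size(); ++k) {
                int ind = rest[k];
                double pi = d.logpred(ind, ysa.data(), ylsa.data());
                double pj = d.logpred(ind, ysb.data(), ylsb.data());
                double li = std::log((double)memi.size()) + pi;
                double lj = std::log((double)memj.size()) + pj;
                double mx = std::max(li, lj);
                double lse = mx + std::log(std::exp(li - mx) + std::exp(lj - mx));
                if (std::log(unif_rand()) < li - lse) {
                    logq += li - lse;
                    logLi += pi;
                    memi.push_back(ind);
                    add_to_scratch(ind, ysa, ylsa);
                } else {
                    logq += lj - lse;
                    logLj += pj;
                    memj.push_back(ind);
                    add_to_scratch(ind, ysb, ylsb);
                }
            }
            int nS = cl.size[c], ni = (int)memi.size(), nj = (int)memj.size();
            // whole-cluster marginal from the maintained counts
            std::vector<int> all(memi);
            all.insert(all.end(), memj.begin(), memj.end());
            double logLS = log_marginal_members(d, all, ysc, ylsc);
            double logacc = std::log(alpha)
                + R::lgammafn((double)ni) + R::lgammafn((double)nj)
                - R::lgammafn((double)nS)
                + logLi + logLj - logLS - logq;
            if (std::log(unif_rand()) < logacc) {
                sams_split_acc++;
                int cnew = cl.new_cluster();
                for (size_t k = 0; k < memj.size(); ++k) {
                    int ind = memj[k];
                    cl.add(ind, c, -1);
                    cl.add(ind, cnew, +1);
                    lab[ind] = cnew;
                }
            }
        } else {  // propose a merge
            sams_merge_prop++;
            int ci = lab[i], cj = lab[j];
            std::vector<int> memi, memj;
            members_of(ci, memi, -1, -1);
            members_of(cj, memj, -1, -1);
            double logLi = log_marginal_members(d, memi, ysc, ylsc);
            double logLj = log_marginal_members(d, memj, ysc, ylsc);
            std::vector<int> all(memi);
            all.insert(all.end(), memj.begin(), memj.end());
            double logLS = log_marginal_members(d, all, ysc, ylsc);
            // replay the reverse split in a random order to get q(eta | eta')
            std::vector<int> rest;
            for (size_t k = 0; k < all.size(); ++k)
                if (all[k] != i && all[k] != j) rest.push_back(all[k]);
            shuffle_in_place(rest);
            std::fill(ysa.begin(), ysa.end(), 0); std::fill(ylsa.begin(), ylsa.end(), 0);
            std::fill(ysb.begin(), ysb.end(), 0); std::fill(ylsb.begin(), ylsb.end(), 0);
            add_to_scratch(i, ysa, ylsa);
            add_to_scratch(j, ysb, ylsb);
            int szi = 1, szj = 1;
            double logq = 0.0;
            for (size_t k = 0; k < rest.size(); ++k) {
                int ind = rest[k];
                double pi = d.logpred(ind, ysa.data(), ylsa.data());
                double pj = d.logpred(ind, ysb.data(), ylsb.data());
                double li = std::log((double)szi) + pi;
                double lj = std::log((double)szj) + pj;
                double mx = std::max(li, lj);
                double lse = mx + std::log(std::exp(li - mx) + std::exp(lj - mx));
                if (lab[ind] == ci) {
                    logq += li - lse;
                    add_to_scratch(ind, ysa, ylsa); szi++;
                } else {
                    logq += lj - lse;
                    add_to_scratch(ind, ysb, ylsb); szj++;
                }
            }
            int nS = (int)all.size(), ni = (int)memi.size(), nj = (int)memj.size();
            double logacc = logq
                + R::lgammafn((double)nS)
                - std::log(alpha) - R::lgammafn((double)ni) - R::lgammafn((double)nj)
                + logLS - logLi - logLj;
            if (std::log(unif_rand()) < logacc) {
                sams_merge_acc++;
                for (size_t k = 0; k < memj.size(); ++k) {
                    int ind = memj[k];
                    cl.add(ind, cj, -1);
                    cl.add(ind, ci, +1);
                    lab[ind] = ci;
                }
                int moved = cl.drop(cj);
                if (moved >= 0)
                    for (int k = 0; k < d.n; ++k)
                        if (lab[k] == moved) lab[k] = cj;
            }
        }
    }

    inline void add_to_scratch(int i, std::vector<int> &ys, std::vector<int> &yls) {
        for (int l = 0; l < d.L; ++l) {
            if (d.J[l] < 1) continue;
            for (int s = 0; s < d.P; ++s) {
                int c = d.geno(i, d.P * l + s);
                if (c >= 0) { ys[d.off[l] + c]++; yls[l]++; }
            }
        }
    }

    // data log-likelihood contribution of locus l under hyperparameter lam
    double locus_loglik(int l, double lam) const {
        double lp = 0.0;
        for (int j = 0; j < cl.K(); ++j)
            lp += dm_locus_loglik(cl.y[j].data() + d.off[l], cl.yl[j][l], d.J[l], lam);
        return lp;
    }

    void lambda_update() {
        if (lambda_mode == 2) {            // unique value per locus
            for (int l = 0; l < d.L; ++l) {
                if (d.J[l] < 1) continue;
                lambda_prop++;
                double prop = d.lambda[l] + norm_rand() * delta;
                if (prop <= 0.0 || prop > lambda_upper) continue;  // prior density 0
                double diff = locus_loglik(l, prop) - locus_loglik(l, d.lambda[l]);
                if (std::log(unif_rand()) < diff) {
                    lambda_acc++;
                    d.lambda[l] = prop;
                    d.build_cache(l);
                }
            }
        } else if (lambda_mode == 1) {     // single value shared by all loci
            lambda_prop++;
            double cur = d.lambda[0];
            double prop = cur + norm_rand() * delta;
            if (prop <= 0.0 || prop > lambda_upper) return;
            double diff = 0.0;
            for (int l = 0; l < d.L; ++l)
                if (d.J[l] >= 1)
                    diff += locus_loglik(l, prop) - locus_loglik(l, cur);
            if (std::log(unif_rand()) < diff) {
                lambda_acc++;
                for (int l = 0; l < d.L; ++l) {
                    d.lambda[l] = prop;
                    d.build_cache(l);
                }
            }
        }
    }

    void check_counts() const {
        Clusters fresh(&d);
        for (int j = 0; j < cl.K(); ++j) fresh.new_cluster();
        for (int i = 0; i < d.n; ++i) {
            if (lab[i] < 0 || lab[i] >= cl.K()) stop("internal error: bad label");
            fresh.add(i, lab[i], +1);
        }
        for (int j = 0; j < cl.K(); ++j) {
            if (fresh.size[j] != cl.size[j]) stop("internal error: cluster size drift");
            if (fresh.y[j] != cl.y[j]) stop("internal error: allele count drift");
        }
    }
};

static void canonical_labels(const std::vector<int> &lab, int *out, int n) {
    std::vector<int> map;
    for (int i = 0; i < n; ++i) {
        int found = -1;
        for (size_t k = 0; k < map.size(); ++k)
            if (map[k] == lab[i]) { found = (int)k; break; }
        if (found < 0) { map.push_back(lab[i]); found = (int)map.size() - 1; }
        out[i] = found + 1;  // 1-based for R
    }
}

// [[Rcpp::export]]
List run_dp_chain(IntegerMatrix g, IntegerVector J, int ploidy,
                  double alpha, NumericVector lambda, int lambda_mode,
                  double delta, double lambda_upper,
                  int iterations, int burnin, int thin,
                  int n_sams, int n_gibbs,
                  IntegerVector init, int check_every) {
    DPChain ch(g, J, ploidy, lambda, alpha, lambda_mode, delta, lambda_upper, init);
    int n = g.nrow(), L = J.size();
    int nsamp = (iterations > burnin) ? (iterations - burnin) / thin : 0;
    IntegerMatrix labs(nsamp, n);
    IntegerVector Ks(nsamp);
    NumericMatrix lams(lambda_mode > 0 ? nsamp : 0, L);
    std::vector<int> canon(n);
    int cycle = std::max(n_sams + n_gibbs, 1);
    int stored = 0;
    for (int t = 1; t <= iterations; ++t) {
        int pos = (t - 1) % cycle;
        bool do_sams = (pos < n_sams) && (n > 1);
        if (do_sams) ch.sams_move(); else ch.gibbs_scan();
        if (ch.lambda_mode > 0) ch.lambda_update();
        if (check_every > 0 && t % check_every == 0) ch.check_counts();
        if (t > burnin && (t - burnin) % thin == 0 && stored < nsamp) {
            canonical_labels(ch.lab, canon.data(), n);
            for (int i = 0; i < n; ++i) labs(stored, i) = canon[i];
            Ks[stored] = ch.cl.K();
            if (lambda_mode > 0)
                for (int l = 0; l < L; ++l) lams(stored, l) = ch.d.lambda[l];
            stored++;
        }
    }
    return List::create(
        _["labels"] = labs, _["K"] = Ks, _["lambda"] = lams,
        _["accept"] = List::create(
            _["sams_split"] = NumericVector::create(ch.sams_split_acc, ch.sams_split_prop),
            _["sams_merge"] = NumericVector::create(ch.sams_merge_acc, ch.sams_merge_prop),
            _["lambda"] = NumericVector::create(ch.lambda_acc, ch.lambda_prop)));
}

// [[Rcpp::export]]
IntegerVector crp_prior_K(int n, double alpha, int draws) {
    IntegerVector out(draws);
    std::vector<double> sizes;
    for (int r = 0; r < draws; ++r) {
        sizes.clear();
        sizes.push_back(1.0);
        for (int i = 2; i <= n; ++i) {
            double tot = (i - 1) + alpha;
            double u = unif_rand() * tot, acc = 0.0;
            int pick = -1;
            for (size_t j = 0; j < sizes.size(); ++j) {
                acc += sizes[j];
                if (u <= acc) { pick = (int)j; break; }
            }
            if (pick < 0) sizes.push_back(1.0);
            else sizes[pick] += 1.0;
        }
        out[r] = (int)sizes.size();
    }
    return out;
}

// ---------------------------------------------------------------------------
// Fixed-K samplers (FUM / FCM)
// ---------------------------------------------------------------------------

static void rdirichlet_into(double *out, const double *shape, int k) {
    double tot = 0.0;
    for (int h = 0; h < k; ++h) {
        out[h] = R::rgamma(shape[h], 1.0);
        tot += out[h];
    }
    if (tot <= 0.0) {  // pathological underflow: fall back to uniform
        for (int h = 0; h < k; ++h) out[h] = 1.0 / k;
        return;
    }
    for (int h = 0; h < k; ++h) {
        out[h] /= tot;
        if (out[h] < 1e-12) out[h] = 1e-12;
    }
    double s = 0.0;
    for (int h = 0; h < k; ++h) s += out[h];
    for (int h = 0; h < k; ++h) out[h] /= s;
}

static double ddirichlet_log(const double *x, const double *shape, int k) {
    double lp = 0.0, s = 0.0;
    for (int h = 0; h < k; ++h) {
        lp += (shape[h] - 1.0) * std::log(x[h]) - R::lgammafn(shape[h]);
        s += shape[h];
    }
    return lp + R::lgammafn(s);
}

// [[Rcpp::export]]
List run_fixedk_chain(IntegerMatrix g, IntegerVector Jv, int ploidy, int K,
                      int model,  // 0 = FUM, 1 = FCM
                      int iterations, int burnin, int thin, int warmup_end,
                      double pa_conc, double f_sd,
                      NumericVector pa_init, NumericVector f_init,
                      bool pa_fix, bool f_fix) {
    int n = g.nrow(), L = Jv.size();
    std::vector<int> J(Jv.begin(), Jv.end()), off(L + 1, 0);
    for (int l = 0; l < L; ++l) off[l + 1] = off[l] + std::max(J[l], 0);
    int totJ = off[L];

    std::vector<double> P(K * totJ);         // P[j*totJ + off[l] + h]
    std::vector<double> logP(K * totJ);
    std::vector<double> Pa(pa_init.begin(), pa_init.end());  // totJ
    std::vector<double> F(f_init.begin(), f_init.end());     // K
    std::vector<int> y(K * totJ), yl(K * L);
    std::vector<int> lab(n, 0);
    std::vector<double> shape(64);

    // initial frequencies from the prior given Pa/F
    for (int j = 0; j < K; ++j)
        for (int l = 0; l < L; ++l) {
            if (J[l] < 1) continue;
            if ((int)shape.size() < J[l]) shape.resize(J[l]);
            double fj = (model == 1) ? (1.0 - F[j]) / F[j] : 0.0;
            for (int h = 0; h < J[l]; ++h)
                shape[h] = (model == 1) ? Pa[off[l] + h] * fj : 1.0;
            rdirichlet_into(&P[j * totJ + off[l]], shape.data(), J[l]);
        }

    int nsamp = (iterations > burnin) ? (iterations - burnin) / thin : 0;
    IntegerMatrix labs(nsamp, n);
    NumericMatrix acc_prob(n, K);   // aligned assignment-count accumulator
    std::vector<int> perm(K), used(K);
    long f_prop = 0, f_acc = 0, pa_prop = 0, pa_acc = 0;
    int stored = 0;

    std::vector<double> w(K), lw(K), wq(K);

    for (int t = 1; t <= iterations; ++t) {
        for (size_t q = 0; q < logP.size(); ++q) logP[q] = std::log(P[q]);
        std::fill(y.begin(), y.end(), 0);
        std::fill(yl.begin(), yl.end(), 0);

        if (t <= warmup_end) {
            // admixture-style warm-up: flat per-individual mixture weights,
            // each allele copy assigned to a cluster independently
            for (int i = 0; i < n; ++i) {
                double tot = 0.0;
                for (int j = 0; j < K; ++j) { wq[j] = R::rgamma(1.0, 1.0); tot += wq[j]; }
                for (int j = 0; j < K; ++j) wq[j] /= tot;
                int best = 0;
                double bestw = -1.0;
                for (int l = 0; l < L; ++l) {
                    if (J[l] < 1) continue;
                    for (int s = 0; s < ploidy; ++s) {
                        int c = g(i, ploidy * l + s);
                        if (c < 0) continue;
                        double wt = 0.0;
                        for (int j = 0; j < K; ++j) {
                            w[j] = wq[j] * P[j * totJ + off[l] + c];
                            wt += w[j];
                        }
                        double u = unif_rand() * wt, a2 = 0.0;
                        int pick = K - 1;
                        for (int j = 0; j < K; ++j) { a2 += w[j]; if (u <= a2) { pick = j; break; } }
                        y[pick * totJ + off[l] + c]++;
                        yl[pick * L + l]++;
                    }
                }
                for (int j = 0; j < K; ++j)
                    if (wq[j] > bestw) { bestw = wq[j]; best = j; }
                lab[i] = best;  // placeholder; warm-up samples are never stored
            }
        } else {
            // strict no-admixture sweep: whole individuals, equal prior 1/K
            for (int i = 0; i < n; ++i) {
                for (int j = 0; j < K; ++j) lw[j] = 0.0;
                for (int l = 0; l < L; ++l) {
                    if (J[l] < 1) continue;
                    for (int s = 0; s < ploidy; ++s) {
                        int c = g(i, ploidy * l + s);
                        if (c < 0) continue;
                        for (int j = 0; j < K; ++j) lw[j] += logP[j * totJ + off[l] + c];
                    }
                }
                int pick = sample_log_weights(lw);
                lab[i] = pick;
                for (int l = 0; l < L; ++l) {
                    if (J[l] < 1) continue;
                    for (int s = 0; s < ploidy; ++s) {
                        int c = g(i, ploidy * l + s);
                        if (c >= 0) { y[pick * totJ + off[l] + c]++; yl[pick * L + l]++; }
                    }
                }
            }
        }

        // allele frequencies | assignments
        for (int j = 0; j < K; ++j) {
            double fj = (model == 1) ? (1.0 - F[j]) / F[j] : 0.0;
            for (int l = 0; l < L; ++l) {
                if (J[l] < 1) continue;
                if ((int)shape.size() < J[l]) shape.resize(J[l]);
                for (int h = 0; h < J[l]; ++h) {
                    double prior = (model == 1) ? Pa[off[l] + h] * fj : 1.0;
                    shape[h] = y[j * totJ + off[l] + h] + prior;
                }
                rdirichlet_into(&P[j * totJ + off[l]], shape.data(), J[l]);
            }
        }

        if (model == 1) {
            // drift parameters F_j: MH on logit scale, uniform prior on (0,1)
            if (!f_fix) for (int j = 0; j < K; ++j) {
                f_prop++;
                double Fc = F[j];
                double x = std::log(Fc / (1.0 - Fc)) + f_sd * norm_rand();
                double Fp = 1.0 / (1.0 + std::exp(-x));
                if (Fp <= 1e-6 || Fp >= 1.0 - 1e-6) continue;
                double fc = (1.0 - Fc) / Fc, fp = (1.0 - Fp) / Fp;
                double diff = 0.0;
                for (int l = 0; l < L; ++l) {
                    if (J[l] < 1) continue;
                    if ((int)shape.size() < J[l]) shape.resize(J[l]);
                    for (int h = 0; h < J[l]; ++h) shape[h] = Pa[off[l] + h] * fp;
                    diff += ddirichlet_log(&P[j * totJ + off[l]], shape.data(), J[l]);
                    for (int h = 0; h < J[l]; ++h) shape[h] = Pa[off[l] + h] * fc;
                    diff -= ddirichlet_log(&P[j * totJ + off[l]], shape.data(), J[l]);
                }
                // Jacobian of the logit transform
                diff += std::log(Fp * (1.0 - Fp)) - std::log(Fc * (1.0 - Fc));
                if (std::log(unif_rand()) < diff) { f_acc++; F[j] = Fp; }
            }
            // ancestral frequencies Pa_l: Dirichlet-neighbourhood MH, flat prior
            if (!pa_fix) for (int l = 0; l < L; ++l) {
                if (J[l] < 2) continue;
                pa_prop++;
                int Jl = J[l];
                std::vector<double> cur(Pa.begin() + off[l], Pa.begin() + off[l] + Jl);
                std::vector<double> prop(Jl), sh(Jl);
                for (int h = 0; h < Jl; ++h) sh[h] = pa_conc * cur[h] + 0.5;
                rdirichlet_into(prop.data(), sh.data(), Jl);
                double diff = 0.0;
                for (int j = 0; j < K; ++j) {
                    double fj = (1.0 - F[j]) / F[j];
                    if ((int)shape.size() < Jl) shape.resize(Jl);
                    for (int h = 0; h < Jl; ++h) shape[h] = prop[h] * fj;
                    diff += ddirichlet_log(&P[j * totJ + off[l]], shape.data(), Jl);
                    for (int h = 0; h < Jl; ++h) shape[h] = cur[h] * fj;
                    diff -= ddirichlet_log(&P[j * totJ + off[l]], shape.data(), Jl);
                }
                // Hastings correction for the asymmetric Dirichlet proposal
                std::vector<double> shp(Jl);
                for (int h = 0; h < Jl; ++h) shp[h] = pa_conc * prop[h] + 0.5;
                diff += ddirichlet_log(cur.data(), shp.data(), Jl)
                      - ddirichlet_log(prop.data(), sh.data(), Jl);
                if (std::log(unif_rand()) < diff) {
                    pa_acc++;
                    for (int h = 0; h < Jl; ++h) Pa[off[l] + h] = prop[h];
                }
            }
        }

        if (t > burnin && (t - burnin) % thin == 0 && stored < nsamp) {
            // align cluster labels to the running assignment-count reference
            // by greedy maximum shared membership
            if (stored == 0) {
                for (int j = 0; j < K; ++j) perm[j] = j;
            } else {
                std::vector<double> score(K * K, 0.0);
                for (int i = 0; i < n; ++i)
                    for (int r = 0; r < K; ++r)
                        score[lab[i] * K + r] += acc_prob(i, r);
                std::fill(used.begin(), used.end(), 0);
                std::vector<int> rowdone(K, 0);
                for (int step = 0; step < K; ++step) {
                    int ba = -1, br = -1;
                    double best = -1.0;
                    for (int a = 0; a < K; ++a) {
                        if (rowdone[a]) continue;
                        for (int r = 0; r < K; ++r) {
                            if (used[r]) continue;
                            if (score[a * K + r] > best) { best = score[a * K + r]; ba = a; br = r; }
                        }
                    }
                    perm[ba] = br;
                    rowdone[ba] = 1;
                    used[br] = 1;
                }
            }
            for (int i = 0; i < n; ++i) {
                int al = perm[lab[i]];
                labs(stored, i) = al + 1;
                acc_prob(i, al) += 1.0;
            }
            stored++;
        }
    }
    if (stored > 0)
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < K; ++j) acc_prob(i, j) /= stored;
    return List::create(
        _["labels"] = labs, _["assign_prob"] = acc_prob,
        _["accept"] = List::create(
            _["F"] = NumericVector::create(f_acc, f_prop),
            _["Pa"] = NumericVector::create(pa_acc, pa_prop)));
}

// ---------------------------------------------------------------------------
// Island-model Wright-Fisher simulator (allele-frequency resolution)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sim_island_chain(int demes, int deme_size, int generations,
                               int loci, int states, double mu, double m) {
    int twoN = 2 * deme_size;
    // freq[l][d][h]
    std::vector<double> freq((size_t)loci * demes * states);
    std::vector<double> p(states), unif(states, 1.0 / states);
    std::vector<int> counts(states);
    for (int l = 0; l < loci; ++l)
        for (int d = 0; d < demes; ++d) {
            rmultinom(twoN, unif.data(), states, counts.data());
            for (int h = 0; h < states; ++h)
                freq[((size_t)l * demes + d) * states + h] = (double)counts[h] / twoN;
        }
    std::vector<double> colsum(states);
    for (int t = 0; t < generations; ++t) {
        for (int l = 0; l < loci; ++l) {
            double *fl = &freq[(size_t)l * demes * states];
            std::fill(colsum.begin(), colsum.end(), 0.0);
            for (int d = 0; d < demes; ++d)
                for (int h = 0; h < states; ++h) colsum[h] += fl[d * states + h];
            for (int d = 0; d < demes; ++d) {
                double *fd = fl + d * states;
                double tot = 0.0;
                for (int h = 0; h < states; ++h) {
                    double immigrant = (colsum[h] - fd[h]) / (demes - 1);
                    double pm = (1.0 - m) * fd[h] + m * immigrant;
                    pm = (1.0 - mu) * pm + mu / states;
                    p[h] = pm;
                    tot += pm;
                }
                for (int h = 0; h < states; ++h) p[h] /= tot;
                rmultinom(twoN, p.data(), states, counts.data());
                for (int h = 0; h < states; ++h) fd[h] = (double)counts[h] / twoN;
            }
        }
    }
    NumericVector out(freq.begin(), freq.end());
    out.attr("dim") = IntegerVector::create(states, demes, loci);
    return out;
}

// ---------------------------------------------------------------------------
// Linear sum assignment (Hungarian algorithm) and partition utilities
// ---------------------------------------------------------------------------

// Minimising Hungarian on an n x m cost matrix (n <= m), shortest augmenting
// path formulation with potentials; returns column matched to each row.
static double hungarian_min(const std::vector<double> &a, int n, int m,
                            std::vector<int> &match_row) {
    std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
    std::vector<int> pcol(m + 1, 0), way(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        pcol[0] = i;
        int j0 = 0;
        std::vector<double> minv(m + 1, R_PosInf);
        std::vector<char> used(m + 1, 0);
        do {
            used[j0] = 1;
            int i0 = pcol[j0], j1 = -1;
            double delta = R_PosInf;
            for (int j = 1; j <= m; ++j) {
                if (used[j]) continue;
                double cur = a[(size_t)(i0 - 1) * m + (j - 1)] - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= m; ++j) {
                if (used[j]) { u[pcol[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (pcol[j0] != 0);
        do { int j1 = way[j0]; pcol[j0] = pcol[j1]; j0 = j1; } while (j0);
    }
    match_row.assign(n, -1);
    double total = 0.0;
    for (int j = 1; j <= m; ++j)
        if (pcol[j] > 0) {
            match_row[pcol[j] - 1] = j - 1;
            total += a[(size_t)(pcol[j] - 1) * m + (j - 1)];
        }
    return total;
}

// [[Rcpp::export]]
List lsap_max(NumericMatrix mat) {
    int n = mat.nrow(), m = mat.ncol();
    bool flip = n > m;
    int r = flip ? m : n, c = flip ? n : m;
    double mx = 0.0;
    for (int i = 0; i < n * m; ++i) mx = std::max(mx, mat[i]);
    std::vector<double> cost((size_t)r * c);
    for (int i = 0; i < r; ++i)
        for (int j = 0; j < c; ++j)
            cost[(size_t)i * c + j] = mx - (flip ? mat(j, i) : mat(i, j));
    std::vector<int> match;
    double tot = hungarian_min(cost, r, c, match);
    double value = r * mx - tot;
    IntegerVector out(n, NA_INTEGER);
    if (!flip) {
        for (int i = 0; i < r; ++i) out[i] = match[i] + 1;
    } else {
        for (int i = 0; i < r; ++i) out[match[i]] = i + 1;
    }
    return List::create(_["total"] = value, _["match"] = out);
}

// maximum total overlap between two labelled partitions under an optimal
// cluster matching, with optional per-individual weights
static double max_overlap(const int *a, const int *b, const double *wt, int n) {
    int Ka = 0, Kb = 0;
    for (int i = 0; i < n; ++i) {
        Ka = std::max(Ka, a[i]);
        Kb = std::max(Kb, b[i]);
    }
    std::vector<double> ov((size_t)Ka * Kb, 0.0);
    for (int i = 0; i < n; ++i)
        ov[(size_t)(a[i] - 1) * Kb + (b[i] - 1)] += wt ? wt[i] : 1.0;
    double mx = 0.0;
    for (size_t q = 0; q < ov.size(); ++q) mx = std::max(mx, ov[q]);
    int r = std::min(Ka, Kb), c = std::max(Ka, Kb);
    std::vector<double> cost((size_t)r * c);
    for (int i = 0; i < r; ++i)
        for (int j = 0; j < c; ++j) {
            double o = (Ka <= Kb) ? ov[(size_t)i * Kb + j] : ov[(size_t)j * Kb + i];
            cost[(size_t)i * c + j] = mx - o;
        }
    std::vector<int> match;
    double tot = hungarian_min(cost, r, c, match);
    return r * mx - tot;
}

// [[Rcpp::export]]
double partition_overlap_cpp(IntegerVector a, IntegerVector b, NumericVector wt) {
    int n = a.size();
    const double *w = (wt.size() == n) ? &wt[0] : (const double *)NULL;
    return max_overlap(&a[0], &b[0], w, n);
}

// Greedy mean-partition search: single-individual moves, strict decreases
// only, sweeps in index order until no improvement.
// samples: v x n matrix of 1-based labels; wt: per-sample multiplicities.
// [[Rcpp::export]]
List mean_partition_cpp(IntegerMatrix samples, NumericVector wt, IntegerVector init,
                        int max_sweeps) {
    int v = samples.nrow(), n = samples.ncol();
    std::vector<std::vector<int> > smp(v, std::vector<int>(n));
    for (int s = 0; s < v; ++s)
        for (int i = 0; i < n; ++i) smp[s][i] = samples(s, i);
    std::vector<int> u(init.begin(), init.end());

    // D(u) = sum over samples of wt_s * (n - maxoverlap(u, eta_s))
    std::vector<int> ubuf(n);
    double D = 0.0;
    for (int s = 0; s < v; ++s)
        D += wt[s] * (n - max_overlap(u.data(), smp[s].data(), NULL, n));

    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        bool improved = false;
        for (int i = 0; i < n; ++i) {
            int K = 0;
            for (int q = 0; q < n; ++q) K = std::max(K, u[q]);
            int cur = u[i];
            double bestD = D;
            int bestLab = cur;
            for (int cand = 1; cand <= K + 1; ++cand) {
                if (cand == cur) continue;
                std::copy(u.begin(), u.end(), ubuf.begin());
                ubuf[i] = cand;
                // renumber so labels stay 1..K' contiguous
                std::vector<int> map(K + 2, 0);
                int next = 0;
                for (int q = 0; q < n; ++q) {
                    if (map[ubuf[q]] == 0) map[ubuf[q]] = ++next;
                    ubuf[q] = map[ubuf[q]];
                }
                double Dp = 0.0;
                for (int s = 0; s < v; ++s) {
                    Dp += wt[s] * (n - max_overlap(ubuf.data(), smp[s].data(), NULL, n));
                    if (Dp >= bestD) break;  // cannot strictly improve
                }
                if (Dp < bestD) { bestD = Dp; bestLab = cand; }
            }
            if (bestLab != cur) {
                u[i] = bestLab;
                std::vector<int> map(n + 2, 0);
                int next = 0;
                for (int q = 0; q < n; ++q) {
                    if (map[u[q]] == 0) map[u[q]] = ++next;
                    u[q] = map[u[q]];
                }
                D = bestD;
                improved = true;
            }
        }
        if (!improved) break;
    }
    return List::create(_["partition"] = IntegerVector(u.begin(), u.end()),
                        _["D"] = D);
}
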