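#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstring>
#include "rng.h"
#include "cascade.h"

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_resolve_cascade(NumericVector V0, IntegerVector isI,
                         IntegerVector ptr, IntegerVector rcv,
                         NumericVector wf, NumericVector ws,
                         LogicalVector blocked, IntegerVector initiators,
                         List par)
{
    const int n = V0.size();
    CascadeParams P;
    P.VL = par["VL"]; P.VE = par["VE"]; P.VI = par["VI"];
    P.VT = par["VT"]; P.Vreset = par["Vreset"]; P.tauV = par["tauV"];

    std::vector<double> V(V0.begin(), V0.end());
    std::vector<char> isIc(n), blk(n);
    for (int i = 0; i < n; ++i) { isIc[i] = (char)isI[i]; blk[i] = (char)blocked[i]; }
    std::vector<int> init(initiators.begin(), initiators.end());
    std::vector<int> firedOrder;
    std::vector<double> slowPend(n, 0.0);
    CascadeWork W;

    resolve_cascade_core(V, isIc, ptr.begin(), rcv.begin(), wf.begin(),
                         ws.size() ? ws.begin() : (double*)nullptr,
                         [&](int i) { return blk[i] != 0; },
                         init, P, false, nullptr, nullptr,
                         firedOrder, slowPend, W);

    return List::create(_["fired"] = wrap(firedOrder),
                        _["V_post"] = wrap(V),
                        _["slow_pending"] = wrap(slowPend));
}

// ---------------------------------------------------------------------------
// Hybrid substep / event-driven network engine.
//
// Between instants every neuron relaxes under leak + its decaying slow
// conductance (exponential substeps with the conductance frozen at the
// substep midpoint; threshold crossings solved in closed form inside a
// substep).  Feedforward Poisson arrivals are instantaneous fast-E jumps at
// their exact times.  Any threshold crossing triggers exact cascade
// resolution over the whole network at that instant (tau_fast = 0), or, in
// the finite fast-timescale mode (tau_fast > 0), a single spike whose fast
// conductances decay with tau_fast.

struct DelayedDelivery {
    double t; int rcv; double wf, ws;
    bool operator>(const DelayedDelivery& o) const { return t > o.t; }
};

struct Engine {
    // network
    int n;
    std::vector<char> isI;
    const int *ptr, *rcvv;
    const double *wf, *ws;
    std::vector<char> isLR;
    // parameters
    double VL, VE, VI, VT, Vreset, tauV, tauRef, tauSlow, tauFast;
    // drive
    std::vector<double> etaBkg;   // per ms
    std::vector<double> contrast, phase, sDrive;
    double period_ms, onset;
    bool phaseFree;
    // config
    double duration, substep, delay;
    // state
    std::vector<double> V, g, gfE, gfI, refUntil;
    std::vector<Xoshiro256pp> drng;
    Xoshiro256pp irng;
    // drive arrival heap
    typedef std::pair<double,int> TN;
    std::priority_queue<TN, std::vector<TN>, std::greater<TN>> heap;
    std::priority_queue<DelayedDelivery, std::vector<DelayedDelivery>,
                        std::greater<DelayedDelivery>> dq;
    // per-substep event bookkeeping
    struct Ev { double t; int i; double jw, sw; int next; };
    std::vector<Ev> evs;
    std::vector<int> evFirst, evLast, evMark;
    int stamp;
    // outputs
    std::vector<double> spkT;
    std::vector<int> spkId, spkInstant;
    int instantId;
    // scratch
    std::vector<double> snapV, snapG, snapGfE, snapGfI;
    std::vector<double> crossT;
    std::vector<double> slowPend;
    CascadeWork cw;
    std::vector<int> firedOrder;

    double rate(int i, double t) const {
        const double bkg = etaBkg[i];
        if (t < onset || contrast[i] <= 0.0) return bkg;
        if (phaseFree) return bkg * (1.0 + contrast[i]);
        const double s = std::sin(2.0 * M_PI * (t - phase[i]) / period_ms);
        return bkg + contrast[i] * bkg * (1.0 + s);
    }
    double supRate(int i) const {
        return etaBkg[i] * (1.0 + contrast[i] * (phaseFree ? 1.0 : 2.0));
    }
    void scheduleArrival(int i, double tprev) {
        const double sup = supRate(i);
        if (sup <= 0.0) return;
        double t = tprev;
        for (;;) {
            t += drng[i].expo(sup);
            if (t > duration) return;
            if (drng[i].unif() < rate(i, t) / sup) { heap.push(TN(t, i)); return; }
        }
    }

    // cached decay factors for the most recent piece length (pieces within
    // one pass share their length for all event-free neurons)
    double cacheDt = -1.0, cSlowHalf = 1.0, cSlowFull = 1.0,
           cFastHalf = 1.0, cFastFull = 1.0, cLeak = 1.0;
    void setPieceCache(double dt) {
        cacheDt = dt;
        cSlowHalf = std::exp(-0.5 * dt / tauSlow);
        cSlowFull = cSlowHalf * cSlowHalf;
        if (tauFast > 0.0) {
            cFastHalf = std::exp(-0.5 * dt / tauFast);
            cFastFull = cFastHalf * cFastHalf;
        }
        cLeak = std::exp(-dt / tauV);
    }
    // exp(-x) for small x >= 0 (x = g_mid * dt / tauV stays well below 1)
    static inline double expSmall(double x) {
        if (x > 0.04) return std::exp(-x);
        return 1.0 - x * (1.0 - 0.5 * x * (1.0 - x / 3.0 * (1.0 - 0.25 * x)));
    }

    // integrate one event-free piece [t0, t1); returns crossing time or inf
    double piece(int i, double t0, double t1) {
        const double dt = t1 - t0;
        if (dt <= 0.0) return R_PosInf;
        if (dt != cacheDt) setPieceCache(dt);
        double denom, Vs;
        if (tauFast <= 0.0) {
            const double gm = g[i] * cSlowHalf;
            denom = 1.0 + gm;
            Vs = (VL + gm * VE) / denom;
            g[i] *= cSlowFull;
        } else {
            const double gm  = g[i]   * cSlowHalf;
            const double gem = gfE[i] * cFastHalf;
            const double gim = gfI[i] * cFastHalf;
            denom = 1.0 + gm + gem + gim;
            Vs = (VL + (gm + gem) * VE + gim * VI) / denom;
            g[i]   *= cSlowFull;
            gfE[i] *= cFastFull;
            gfI[i] *= cFastFull;
        }
        const double f = cLeak * expSmall((denom - 1.0) * dt / tauV);
        const double Vnew = Vs + (V[i] - Vs) * f;
        if (Vnew >= VT && V[i] < VT) {
            const double tc = t0 - (tauV / denom) * std::log((VT - Vs) / (V[i] - Vs));
            V[i] = VT;
            return tc;
        }
        V[i] = Vnew;
        return (V[i] >= VT) ? t0 : R_PosInf;
    }

    // advance neuron i across [ta, tb), applying its arrivals; returns first
    // crossing time (inf if none); on crossing the neuron is left at VT
    double advance(int i, double ta, double tb) {
        double t = ta;
        // refractory handling: voltage clamped, all synaptic input ignored
        if (refUntil[i] >= tb) {
            const double dt = tb - t;
            g[i] *= std::exp(-dt / tauSlow);
            if (tauFast > 0.0) {
                gfE[i] *= std::exp(-dt / tauFast);
                gfI[i] *= std::exp(-dt / tauFast);
            }
            V[i] = Vreset;
            return R_PosInf;
        }
        if (refUntil[i] > t) {
            const double dt = refUntil[i] - t;
            g[i] *= std::exp(-dt / tauSlow);
            if (tauFast > 0.0) {
                gfE[i] *= std::exp(-dt / tauFast);
                gfI[i] *= std::exp(-dt / tauFast);
            }
            V[i] = Vreset;
            t = refUntil[i];
        }
        if (evMark[i] == stamp) {
            for (int e = evFirst[i]; e >= 0; e = evs[e].next) {
                const double te = evs[e].t;
                if (te < t) continue;          // fell inside refractory: ignored
                if (te >= tb) break;
                const double tc = piece(i, t, te);
                if (R_FINITE(tc)) return tc;
                t = te;
                if (tauFast <= 0.0) {
                    V[i] = VE + (V[i] - VE) * std::exp(-evs[e].jw / tauV);
                    if (evs[e].sw > 0.0) g[i] += evs[e].sw / tauSlow;
                    if (V[i] >= VT) return te;
                } else {
                    gfE[i] += evs[e].jw / tauFast;
                    if (evs[e].sw > 0.0) g[i] += evs[e].sw / tauSlow;
                }
            }
        }
        return piece(i, t, tb);
    }

    void snapshot() {
        snapV = V; snapG = g;
        if (tauFast > 0.0) { snapGfE = gfE; snapGfI = gfI; }
    }
    void restore() {
        V = snapV; g = snapG;
        if (tauFast > 0.0) { gfE = snapGfE; gfI = snapGfI; }
    }

    // per-substep lazy positions: each neuron's state is valid at localT[i]
    std::vector<double> localT;

    // advance neuron i without mutating its state; returns first crossing
    double scanAdvance(int i, double ta, double tb) {
        const double sV = V[i], sG = g[i];
        double sE = 0, sI2 = 0;
        if (tauFast > 0.0) { sE = gfE[i]; sI2 = gfI[i]; }
        const double tc = advance(i, ta, tb);
        V[i] = sV; g[i] = sG;
        if (tauFast > 0.0) { gfE[i] = sE; gfI[i] = sI2; }
        return tc;
    }

    void fireInstant(double tstar, std::vector<int>& inits) {
        ++instantId;
        if (tauFast <= 0.0) {
            // order simultaneous initiators by voltage surplus, random tie-break
            if (inits.size() > 1) {
                for (size_t k = inits.size() - 1; k > 0; --k) {
                    size_t j = (size_t)(irng.unif() * (k + 1));
                    std::swap(inits[k], inits[j]);
                }
                std::stable_sort(inits.begin(), inits.end(),
                                 [&](int a2, int b2) { return V[a2] > V[b2]; });
            }
            CascadeParams P{VL, VE, VI, VT, Vreset, tauV};
            firedOrder.clear();
            const bool skipLR = (delay > 0.0);
            resolve_cascade_core(V, isI, ptr, rcvv, wf, ws,
                                 [&](int i) { return refUntil[i] > tstar; },
                                 inits, P,
                                 skipLR, skipLR ? isLR.data() : nullptr,
                                 [&](int r) {     // lazy: bring r up to tstar
                                     if (localT[r] < tstar) {
                                         advance(r, localT[r], tstar);
                                         localT[r] = tstar;
                                     }
                                 },
                                 firedOrder, slowPend, cw);
            for (int i : firedOrder) {
                refUntil[i] = tstar + tauRef;
                localT[i] = tstar;
                spkT.push_back(tstar); spkId.push_back(i);
                spkInstant.push_back(instantId);
                if (skipLR) {
                    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
                        if (!isLR[e]) continue;
                        dq.push(DelayedDelivery{tstar + delay, rcvv[e], wf[e], ws[e]});
                    }
                }
            }
            for (int i : cw.touchedList) {
                if (slowPend[i] > 0.0 && refUntil[i] <= tstar)
                    g[i] += slowPend[i] / tauSlow;
                slowPend[i] = 0.0;
            }
            for (int i : firedOrder) slowPend[i] = 0.0;
        } else {
            // finite fast timescale: no instantaneous cascade; each initiator
            // fires individually and its conductances decay with tauFast
            cw.ensure(n);
            cw.touchedList.clear();
            for (int i : inits) {
                if (refUntil[i] > tstar) continue;
                spkT.push_back(tstar); spkId.push_back(i);
                spkInstant.push_back(instantId);
                V[i] = Vreset;
                refUntil[i] = tstar + tauRef;
                localT[i] = tstar;
                const char senderI = isI[i];
                for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
                    const int r = rcvv[e];
                    if (refUntil[r] > tstar) continue;
                    if (delay > 0.0 && isLR[e]) {
                        dq.push(DelayedDelivery{tstar + delay, r, wf[e], ws[e]});
                        continue;
                    }
                    if (localT[r] < tstar) {
                        advance(r, localT[r], tstar);
                        localT[r] = tstar;
                    }
                    if (!cw.touched[r]) { cw.touched[r] = 1; cw.touchedList.push_back(r); }
                    if (senderI) gfI[r] += wf[e] / tauFast;
                    else         gfE[r] += wf[e] / tauFast;
                    if (ws[e] > 0.0) g[r] += ws[e] / tauSlow;
                }
            }
            for (int r : cw.touchedList) cw.touched[r] = 0;
        }
    }
};

// [[Rcpp::export]]
List cpp_run_engine(IntegerVector type, IntegerVector clust, int nClust,
                    IntegerVector e_ptr, IntegerVector e_rcv,
                    NumericVector e_wf, NumericVector e_ws, LogicalVector e_lr,
                    NumericVector etaBkgHz, NumericVector contrast,
                    NumericVector phase_ms, double omegaHz, bool phaseFree,
                    double onset_ms, NumericVector sDrive, List par,
                    double duration, double substep, double sampleInterval,
                    int sampleMode, double delay_ms, double seed,
                    double maxSpikes)
{
    Engine E;
    E.n = type.size();
    const int n = E.n;
    E.isI.resize(n);
    for (int i = 0; i < n; ++i) E.isI[i] = (char)type[i];
    E.ptr = e_ptr.begin(); E.rcvv = e_rcv.begin();
    E.wf = e_wf.begin(); E.ws = e_ws.begin();
    E.isLR.resize(e_lr.size());
    for (int i = 0; i < e_lr.size(); ++i) E.isLR[i] = (char)e_lr[i];

    E.VL = par["VL"]; E.VE = par["VE"]; E.VI = par["VI"]; E.VT = par["VT"];
    E.Vreset = par["Vreset"]; E.tauV = par["tauV"]; E.tauRef = par["tauRef"];
    E.tauSlow = par["tauSlow"]; E.tauFast = par["tauFast"];

    E.etaBkg.resize(n); E.contrast.resize(n); E.phase.resize(n); E.sDrive.resize(n);
    for (int i = 0; i < n; ++i) {
        E.etaBkg[i] = etaBkgHz[i] / 1000.0;   // Hz -> per ms
        E.contrast[i] = contrast[i];
        E.phase[i] = phase_ms[i];
        E.sDrive[i] = sDrive[i];
    }
    E.period_ms = 1000.0 / omegaHz;
    E.onset = onset_ms;
    E.phaseFree = phaseFree;
    E.duration = duration; E.substep = substep; E.delay = delay_ms;

    const uint64_t master = (uint64_t)seed;
    E.irng.init(stream_seed(master, 1));
    Xoshiro256pp icrng; icrng.init(stream_seed(master, 0));

    E.V.resize(n); E.g.assign(n, 0.0); E.refUntil.assign(n, -1e18);
    if (E.tauFast > 0.0) { E.gfE.assign(n, 0.0); E.gfI.assign(n, 0.0); }
    for (int i = 0; i < n; ++i)
        E.V[i] = E.Vreset + (0.95 * E.VT - E.Vreset) * icrng.unif();

    E.drng.resize(n);
    for (int i = 0; i < n; ++i) {
        E.drng[i].init(stream_seed(master, 2 + (uint64_t)i));
        E.scheduleArrival(i, 0.0);
    }

    E.localT.assign(n, 0.0);
    E.evFirst.assign(n, -1); E.evLast.assign(n, -1); E.evMark.assign(n, -1);
    E.stamp = 0;
    E.instantId = 0;
    E.slowPend.assign(n, 0.0);
    E.crossT.assign(n, R_PosInf);

    // sampling setup
    std::vector<double> sampT;
    std::vector<double> clustV;   // samples x (nClust*2), row-major
    std::vector<double> fullV;    // samples x n, row-major
    std::vector<std::vector<int>> members(nClust * 2);
    for (int i = 0; i < n; ++i) members[clust[i] * 2 + type[i]].push_back(i);
    long sampEvery = 0;
    if (sampleInterval > 0.0)
        sampEvery = (long)std::lround(sampleInterval / substep);

    const long nSub = (long)std::ceil(duration / substep - 1e-9);
    for (long k = 0; k < nSub; ++k) {
        if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
        const double t0 = k * substep;
        const double t1 = std::min((k + 1) * substep, duration);

        // gather this substep's events (drive arrivals + delayed deliveries)
        ++E.stamp;
        E.evs.clear();
        auto addEv = [&](double t, int i, double jw, double sw) {
            Engine::Ev ev{t, i, jw, sw, -1};
            const int idx = (int)E.evs.size();
            E.evs.push_back(ev);
            if (E.evMark[i] != E.stamp) {
                E.evMark[i] = E.stamp; E.evFirst[i] = idx; E.evLast[i] = idx;
            } else {
                E.evs[E.evLast[i]].next = idx; E.evLast[i] = idx;
            }
        };
        while (!E.heap.empty() && E.heap.top().first < t1) {
            const double t = E.heap.top().first;
            const int i = E.heap.top().second;
            E.heap.pop();
            addEv(t, i, E.sDrive[i], 0.0);
            E.scheduleArrival(i, t);
        }
        while (!E.dq.empty() && E.dq.top().t < t1) {
            const DelayedDelivery d = E.dq.top(); E.dq.pop();
            addEv(d.t, d.rcv, d.wf, d.ws);
        }
        // per-neuron event chains must be in time order; heap pops are
        // globally time-ordered but the two sources interleave: rebuild
        // chains sorted if delayed deliveries are present
        if (!E.dq.empty() || E.delay > 0.0) {
            std::vector<int> order(E.evs.size());
            for (size_t z = 0; z < order.size(); ++z) order[z] = (int)z;
            std::stable_sort(order.begin(), order.end(),
                             [&](int a2, int b2) { return E.evs[a2].t < E.evs[b2].t; });
            ++E.stamp;
            std::vector<Engine::Ev> evs2; evs2.reserve(E.evs.size());
            for (int oz : order) evs2.push_back(E.evs[oz]);
            E.evs.swap(evs2);
            for (size_t z = 0; z < E.evs.size(); ++z) {
                E.evs[z].next = -1;
                const int i = E.evs[z].i;
                if (E.evMark[i] != E.stamp) {
                    E.evMark[i] = E.stamp; E.evFirst[i] = (int)z; E.evLast[i] = (int)z;
                } else {
                    E.evs[E.evLast[i]].next = (int)z; E.evLast[i] = (int)z;
                }
            }
        }

        // optimistic pass: advance everyone through the substep, tracking
        // each neuron's first threshold crossing
        E.snapshot();
        double tstar = R_PosInf;
        for (int i = 0; i < n; ++i) {
            const double tc = E.advance(i, t0, t1);
            E.crossT[i] = tc;
            if (tc < tstar) tstar = tc;
        }
        if (R_FINITE(tstar)) {
            // crossings: rewind, then handle instants one by one, advancing
            // only the neurons each cascade touches (lazy positions localT)
            E.restore();
            std::fill(E.localT.begin(), E.localT.end(), t0);
            double tprev = -1.0;
            while (R_FINITE(tstar)) {
                std::vector<int> inits;
                for (int i = 0; i < n; ++i) {
                    if (E.crossT[i] == tstar) {
                        if (E.localT[i] < tstar) {
                            E.advance(i, E.localT[i], tstar);
                            E.localT[i] = tstar;
                        }
                        E.V[i] = E.VT;
                        inits.push_back(i);
                    }
                }
                E.fireInstant(tstar, inits);
                // refresh crossing times for everyone the instant moved
                for (int i : E.cw.touchedList) {
                    E.crossT[i] = (E.localT[i] < t1)
                        ? E.scanAdvance(i, E.localT[i], t1) : R_PosInf;
                    if (E.crossT[i] <= tstar)  // numerical guard: strictly later
                        E.crossT[i] = std::nextafter(tstar, t1);
                }
                for (int i : inits) E.crossT[i] = (E.localT[i] < t1)
                    ? E.scanAdvance(i, E.localT[i], t1) : R_PosInf;
                tprev = tstar;
                tstar = R_PosInf;
                for (int i = 0; i < n; ++i)
                    if (E.crossT[i] > tprev && E.crossT[i] < tstar)
                        tstar = E.crossT[i];
            }
            // commit: bring everyone to the substep end
            for (int i = 0; i < n; ++i)
                if (E.localT[i] < t1) E.advance(i, E.localT[i], t1);
            std::fill(E.localT.begin(), E.localT.end(), t1);
        }

        // NaN / runaway guard
        if ((k & 255) == 0) {
            double v0 = E.V[0];
            if (!R_FINITE(v0)) stop("non-finite voltage at t=%f ms", t1);
        }
        if ((double)E.spkT.size() > maxSpikes)
            stop("runaway regime: spike count exceeded %g by t=%.1f ms "
                 "(mean rate %.1f Hz/neuron)", maxSpikes, t1,
                 (double)E.spkT.size() / n / t1 * 1000.0);

        if (sampEvery > 0 && ((k + 1) % sampEvery == 0)) {
            sampT.push_back(t1);
            for (int c = 0; c < nClust * 2; ++c) {
                double s = 0.0;
                for (int i : members[c]) s += E.V[i];
                clustV.push_back(members[c].empty() ? 0.0 : s / members[c].size());
            }
            if (sampleMode >= 2)
                for (int i = 0; i < n; ++i) fullV.push_back(E.V[i]);
        }
    }

    List out = List::create(
        _["spike_t"] = wrap(E.spkT),
        _["spike_id"] = wrap(E.spkId),
        _["spike_instant"] = wrap(E.spkInstant),
        _["sample_t"] = wrap(sampT),
        _["cluster_V"] = wrap(clustV),
        _["n_instants"] = E.instantId);
    if (sampleMode >= 2) out["full_V"] = wrap(fullV);
    return out;
}
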