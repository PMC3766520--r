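#ifndef MFESIM_CASCADE_H
#define MFESIM_CASCADE_H

#include <vector>
#include <functional>
#include "rng.h"

// Exact event-driven resolution of one multiple-firing event (MFE) in the
// instantaneous fast-synapse limit.
//
// Every fast kernel is an exponential with the same decay constant, so in
// the rescaled within-instant time u = t / tau_fast the membrane equation of
// a neuron receiving total remaining excitatory area a and inhibitory area b
// reduces (as tau_fast -> 0, leak and slow currents frozen) to
//     dV/du = -(1/tau_V) e^{-u} [ a (V - V_E) + b (V - V_I) ].
// Substituting s = e^{-u} (the fraction of the pending area still
// undelivered) gives a linear constant-coefficient ODE whose solution is
//     V(s) = V* + (V(1) - V*) exp(c (s - 1)),
//     c = (a + b)/tau_V,  V* = (a V_E + b V_I)/(a + b),
// monotone toward V* as s decreases from 1 to 0.  Threshold crossings
// therefore have closed-form within-instant times, and the cascade is
// resolved exactly: repeatedly find the earliest crossing among all neurons,
// advance every touched neuron to that instant, fire the crossing neuron,
// and add its outgoing fast weights to its targets' pending areas.

struct CascadeParams {
    double VL, VE, VI, VT, Vreset, tauV;
};

struct CascadeWork {
    std::vector<double> a, b;      // pending fast E/I areas per neuron
    std::vector<char>   touched;
    std::vector<int>    touchedList;
    void ensure(int n) {
        if ((int)a.size() < n) {
            a.assign(n, 0.0); b.assign(n, 0.0); touched.assign(n, 0);
        }
    }
};

// V          : voltages (mutated; fired neurons end at Vreset)
// isI        : 1 if neuron is inhibitory (sender type -> reversal choice)
// ptr/rcv/wf : CSC adjacency by sender; wf fast weights, ws slow weights
// blocked    : predicate, true if neuron cannot fire or receive
//              (refractory outside this instant)
// initiators : neurons at/above threshold at the opening of the instant,
//              already ordered (caller handles surplus ordering/tie-break)
// skipLR/isLR: when skipLR, edges flagged long-range are not delivered here
//              (the caller schedules them after a horizontal delay)
// onTouch    : called once when a neuron is first touched, before its
//              voltage is used (lets the caller lazily bring that neuron's
//              state up to the cascade instant); may be empty
// firedOrder : output, firing order within the instant
// slowPend   : accumulates slow-weight areas earned by receivers (entries
//              for neurons in the final touched/fired lists only); fired
//              neurons' entries are zeroed -- they are refractory at instant
//              end and receive nothing.  The caller applies and then resets
//              the touched entries.
// After the call W.touchedList still holds every neuron that received fast
// input (fired initiators excluded unless they were touched); the caller may
// use it and must not rely on it across calls.
void resolve_cascade_core(std::vector<double>& V,
                          const std::vector<char>& isI,
                          const int* ptr, const int* rcv,
                          const double* wf, const double* ws,
                          const std::function<bool(int)>& blocked,
                          const std::vector<int>& initiators,
                          const CascadeParams& P,
                          bool skipLR, const char* isLR,
                          const std::function<void(int)>& onTouch,
                          std::vector<int>& firedOrder,
                          std::vector<double>& slowPend,
                          CascadeWork& W);

#endif
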