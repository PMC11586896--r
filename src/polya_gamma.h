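#ifndef OBDSUB_POLYA_GAMMA_H
#define OBDSUB_POLYA_GAMMA_H

struct PG1State {
  double z;          // |z|/2, the J* tilting parameter
  double K;          // rate of the exponential tail proposal
  double p_over_pq;  // mixture weight of the tail proposal
};

void pg1_setup(double z, PG1State& st);
double pg1_draw(const PG1State& st);
double rpg1(double z);

#endif
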