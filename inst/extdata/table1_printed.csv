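region,row,family,lags,loglik,p,bic,delta_bic
Europe,1,exponential_additive,0,20.70,3,-32.89,6.94
Europe,2,exponential_additive,0+1,21.57,4,-31.81,8.02
Europe,3,ricker_lateral,0,23.97,5,-33.77,6.06
Europe,4,ricker_lateral,0+1,27.00,5,-39.83,0.00
British Islands,1,exponential_additive,0,15.90,3,-23.31,32.02
British Islands,2,exponential_additive,0+1,17.60,4,-23.86,31.47
British Islands,3,ricker_lateral,0,19.48,5,-24.80,30.53
British Islands,4,ricker_lateral,0+1,36.17,6,-55.33,0.00
Scandinavian Region,1,exponential_additive,0,18.30,3,-28.10,6.09
Scandinavian Region,2,exponential_additive,0+1,19.30,4,-27.27,6.92
Scandinavian Region,3,ricker_lateral,0,20.77,5,-27.36,6.83
Scandinavian Region,4,ricker_lateral,0+1,25.59,6,-34.19,0.00
France,1,exponential_additive,0,2.78,3,2.94,1.26
France,2,exponential_additive,0+1,3.92,4,3.50,1.82
France,3,ricker_lateral,0,5.41,5,3.34,1.66
France,4,ricker_lateral,0+1,7.66,6,1.68,0.00
Belgium and the Netherlands,1,exponential_additive,0,14.72,3,-20.93,11.27
Belgium and the Netherlands,2,exponential_additive,0+1,15.68,4,-20.02,12.18
Belgium and the Netherlands,3,ricker_lateral,0,17.38,5,-20.59,11.61
Belgium and the Netherlands,4,ricker_lateral,0+1,23.18,5,-32.20,0.00
Germany,1,exponential_additive,0,14.72,3,-20.93,1.74
Germany,2,exponential_additive,0+1,15.23,4,-19.14,3.53
Germany,3,ricker_lateral,0,15.47,5,-16.77,5.90
Germany,4,ricker_lateral,0+1,18.42,5,-22.67,0.00
Spain,1,exponential_additive,0,18.33,3,-28.16,0.00
Spain,2,exponential_additive,0+1,18.97,4,-26.60,1.56
Spain,3,ricker_lateral,0,20.31,5,-26.46,1.70
Spain,4,ricker_lateral,0+1,20.86,5,-27.56,0.60
Italy,1,exponential_additive,0,17.85,3,-27.22,6.67
Italy,2,exponential_additive,0+1,18.56,4,-25.78,8.11
Italy,3,ricker_lateral,0,20.03,5,-25.89,8.00
Italy,4,ricker_lateral,0+1,25.44,6,-33.89,0.00
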