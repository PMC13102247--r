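compound_id,ADT,iDock,LeDock,Qvina,Smina,Vina,PLANTS
IMPHY000749,-5.8,-5.63,-4.29,-5.5,-6.36168718,-5.516,-23.1232
IMPHY001112,-9.01,-6.53,-4.24,-6.4,-6.56255293,-6.485,-23.3898
IMPHY001137,-7.27,-5.7,-3.12,-5.5,-5.51428986,-5.576,-19.641
IMPHY002235,-8.18,-5.41,-3.62,-5.3,-5.54429579,-5.353,-19.9147
IMPHY002354,-7.76,-6.43,-3.84,-6.3,-6.31967449,-6.354,-23.4891
IMPHY003213,-9.36,-7.15,-4.72,-7,-7.80591774,-7.029,-25.2588
IMPHY003388,-10.78,-7.75,-5.99,-7.6,-8.89089966,-7.639,-30.5046
IMPHY003529,-9.77,-6.62,-4.59,-6.5,-6.87833834,-6.423,-25.5034
IMPHY004244,-9.24,-6.16,-4.1,-6.1,-6.33682346,-6.143,-22.2548
IMPHY004515,-8.79,-7.1,-4.54,-6.8,-7.44745255,-6.917,-26.2779
IMPHY004657,-8.23,-6.73,-4.35,-6.6,-6.57699776,-6.539,-23.3057
IMPHY004740,-10.8,-5.86,-5.48,-5.6,-6.49073839,-5.455,-30.8556
IMPHY004834,-10.26,-6.89,-5.5,-6.7,-7.69255066,-6.724,-32.6407
IMPHY004879,-8.12,-5.52,-5.04,-5.4,-6.0210104,-5.457,-24.3221
IMPHY005033,-8.41,-6.9,-4.91,-6.7,-7.57105207,-6.753,-26.9581
IMPHY006072,-9.32,-6.03,-4.37,-5.9,-6.21307039,-5.822,-24.5431
IMPHY006688,-8.38,-6.44,-3.84,-6.4,-6.4461484,-6.464,-22.3314
IMPHY006882,-7.51,-7.48,-4.09,-7.3,-7.28467226,-7.299,-22.5238
IMPHY006927,-7.33,-6.86,-4.08,-6.7,-6.67527962,-6.648,-26.4132
IMPHY007665,-8.22,-6.89,-4.64,-6.7,-7.18536901,-6.641,-25.8599
IMPHY010091,-7.14,-7.04,-3.64,-6.9,-6.87120056,-6.905,-21.443
IMPHY011624,-8.89,-5.72,-3.66,-5.6,-5.78597546,-5.649,-23.5078
IMPHY012536,-11.55,-7.14,-5.42,-7.2,-7.66504097,-7.226,-28.6494
IMPHY013006,-7.41,-6.4,-3.48,-6.2,-6.41249418,-6.23,-24.9737
IMPHY013015,-7.72,-6.84,-4.18,-6.8,-6.9606986,-6.609,-26.4065
IMPHY013285,-9.54,-6.49,-4.84,-6.3,-7.00919008,-6.363,-28.2672
IMPHY013601,-8.98,-6.81,-3.92,-6.6,-6.80245543,-6.657,-24.6636
IMPHY014026,-3.5,-3.66,-5.35,-3.5,-2.1,-3.4,-20.11
IMPHY014076,-12.36,-6.84,-5.35,-6.8,-8.01279831,-6.555,-28.1998
IMPHY014146,-7.91,-7.24,-4.27,-7.1,-7.05308867,-7.168,-26.5452
IMPHY014498,-12.23,-8.25,-5.54,-8,-8.70506573,-8.038,-31.58
IMPHY014981,-7.76,-6.37,-3.77,-6.2,-6.22190332,-6.254,-21.5916
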